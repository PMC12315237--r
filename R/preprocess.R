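# Fit-on-train / apply-everywhere preprocessing for the neural-network path:
# Gauss-rank normalisation, one-hot encoding with an unknown class, median
# imputation and the dropped-feature rule. Tree models bypass all of this.

# Fixed vocabularies of the discrete L2C features (plus an unknown class each).
DISCRETE_VOCABS <- list(
  mr_dx = DX_LEVELS, best_dx = DX_LEVELS, worst_dx = DX_LEVELS,
  sex = c("male", "female"), marital = c("married", "not_married"),
  apoe4_count = c("0", "1", "2"), milder = c("0", "1")
)
UNKNOWN_CLASS <- "unknown"
FNN_DROP_DEFAULT <- "time_since_milder"

#' Fit a Gauss-rank quantile map
#'
#' Maps the empirical distribution of a training column onto a standard
#' Gaussian: the value of (averaged, tie-corrected) rank `r` out of `n` maps
#' to `qnorm((r - 0.5) / n)`. Unique values and their scores are stored as
#' interpolation knots; out-of-range values clip to the extreme scores.
#'
#' @param train_values Numeric training values (NA dropped); needs >= 2
#'   finite values.
#' @return A `gauss_rank_map` with `values` and `scores` knots.
#' @export
fit_gauss_rank <- function(train_values) {
  x <- train_values[is.finite(train_values)]
  if (length(x) < 2) stop("need at least two finite training values")
  if (length(unique(x)) == 1) {
    warning("constant training column; Gauss-rank map degenerates to 0")
    return(structure(list(values = unique(x), scores = 0),
                     class = "gauss_rank_map"))
  }
  n <- length(x)
  r <- rank(x, ties.method = "average")
  s <- stats::qnorm((r - 0.5) / n)
  ord <- order(x)
  xs <- x[ord]; ss <- s[ord]
  keep <- !duplicated(xs)
  structure(list(values = xs[keep], scores = ss[keep]),
            class = "gauss_rank_map")
}

#' Apply / invert a Gauss-rank map
#'
#' Forward interpolates values to Gaussian scores (clipping outside the
#' training range); `inverse_gauss_rank()` interpolates scores back to the
#' original scale. Round trips on in-range training values are exact up to
#' interpolation tolerance. Missing values pass through.
#'
#' @param map A `gauss_rank_map` from [fit_gauss_rank()].
#' @param values,scores Numeric vectors.
#' @return Transformed numeric vector.
#' @export
apply_gauss_rank <- function(map, values) {
  if (length(map$values) == 1) {
    out <- rep(0, length(values)); out[is.na(values)] <- NA; return(out)
  }
  stats::approx(map$values, map$scores, xout = values, rule = 2)$y
}

#' @rdname apply_gauss_rank
#' @export
inverse_gauss_rank <- function(map, scores) {
  if (length(map$values) == 1) {
    out <- rep(map$values, length(scores)); out[is.na(scores)] <- NA; return(out)
  }
  stats::approx(map$scores, map$values, xout = scores, rule = 2)$y
}

#' One-hot encode with an unknown class
#'
#' Encodes over `vocabulary` plus a trailing unknown indicator; missing or
#' unseen values set the unknown indicator, so exactly one indicator is set
#' for every input.
#'
#' @param values Character (or coercible) vector.
#' @param vocabulary Character vocabulary fixed at fit time.
#' @return Matrix with `length(vocabulary) + 1` columns.
#' @export
encode_discrete <- function(values, vocabulary) {
  values <- as.character(values)
  idx <- match(values, vocabulary)
  idx[is.na(idx)] <- length(vocabulary) + 1L
  out <- matrix(0, nrow = length(values), ncol = length(vocabulary) + 1L,
                dimnames = list(NULL, c(vocabulary, UNKNOWN_CLASS)))
  out[cbind(seq_along(idx), idx)] <- 1
  out
}

#' Impute missing values with a training median
#'
#' @param values Numeric vector.
#' @param train_median Median computed on training rows only.
#' @return `values` with `NA` replaced by `train_median`.
#' @export
impute_median <- function(values, train_median) {
  if (is.na(train_median)) stop("training median unavailable (all-missing column)")
  values[is.na(values)] <- train_median
  values
}

#' Drop configured high-missingness columns
#'
#' The neural-network path removes `time_since_milder` (dominated by its 999
#' sentinel / missing diagnosis history); tree-model paths keep all 70
#' features.
#'
#' @param features Feature tibble.
#' @param drop_list Character vector of columns to drop.
#' @return `features` without the listed columns.
#' @export
drop_high_missing <- function(features, drop_list = FNN_DROP_DEFAULT) {
  features[, setdiff(names(features), drop_list), drop = FALSE]
}

#' Fit the neural-network preprocessing state on training rows
#'
#' Learns, from training rows only: per-numeric-feature training medians and
#' Gauss-rank maps (imputation precedes the rank transform), the fixed
#' discrete vocabularies (with unknown class), the dropped-feature list, and
#' Gauss-rank maps for the regression targets (MMSE, ICV-normalised
#' ventricle). Applying the state to its own training rows yields a design
#' matrix with no missing values.
#'
#' @param features Training feature tibble (70 L2C columns).
#' @param targets Optional list/tibble with numeric `mmse` and
#'   `ventricle_icv` training targets for the target maps.
#' @param drop_list Columns removed before encoding (default
#'   `time_since_milder`).
#' @return An `l2c_preprocess` state.
#' @export
fit_preprocess <- function(features, targets = NULL,
                           drop_list = FNN_DROP_DEFAULT) {
  features <- drop_high_missing(features[, l2c_feature_names()], drop_list)
  discrete <- intersect(names(DISCRETE_VOCABS), names(features))
  numeric_cols <- setdiff(names(features), discrete)
  medians <- vapply(numeric_cols,
                    function(col) stats::median(features[[col]], na.rm = TRUE),
                    numeric(1))
  maps <- lapply(numeric_cols, function(col) {
    x <- impute_median(features[[col]], medians[[col]])
    suppressWarnings(fit_gauss_rank(x))
  })
  names(maps) <- numeric_cols
  target_maps <- NULL
  if (!is.null(targets)) {
    target_maps <- lapply(targets, function(y) {
      y <- y[!is.na(y)]
      suppressWarnings(fit_gauss_rank(y))
    })
  }
  design_cols <- c(numeric_cols,
                   unlist(lapply(discrete, function(col)
                     paste(col, c(DISCRETE_VOCABS[[col]], UNKNOWN_CLASS),
                           sep = "."))))
  structure(list(numeric_cols = numeric_cols, discrete_cols = discrete,
                 medians = medians, maps = maps,
                 vocabs = DISCRETE_VOCABS[discrete],
                 drop_list = drop_list, target_maps = target_maps,
                 design_cols = design_cols),
            class = "l2c_preprocess")
}

#' Apply a fitted preprocessing state
#'
#' Imputation, Gauss-rank and one-hot encoding all use statistics learned on
#' the training rows; no statistic is recomputed from the rows being
#' transformed.
#'
#' @param state An `l2c_preprocess` state.
#' @param features Feature tibble (70 L2C columns).
#' @return Numeric design matrix with the state's fixed column layout.
#' @export
apply_preprocess <- function(state, features) {
  missing_cols <- setdiff(c(state$numeric_cols, state$discrete_cols),
                          names(features))
  if (length(missing_cols) > 0) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- vapply(state$numeric_cols, function(col) {
    x <- impute_median(as.numeric(features[[col]]), state$medians[[col]])
    apply_gauss_rank(state$maps[[col]], x)
  }, numeric(nrow(features)))
  if (nrow(features) == 1) num <- matrix(num, nrow = 1,
                                         dimnames = list(NULL, state$numeric_cols))
  disc <- lapply(state$discrete_cols, function(col) {
    m <- encode_discrete(features[[col]], state$vocabs[[col]])
    colnames(m) <- paste(col, colnames(m), sep = ".")
    m
  })
  out <- do.call(cbind, c(list(num), disc))
  stopifnot(identical(colnames(out), state$design_cols))
  out
}

#' Serialise / read a preprocessing state as JSON
#'
#' @param state An `l2c_preprocess` state.
#' @param path JSON path.
#' @return `path` (write) or an `l2c_preprocess` state (read).
#' @export
write_preprocess <- function(state, path) {
  payload <- list(
    version = 1L,
    numeric_cols = state$numeric_cols, discrete_cols = state$discrete_cols,
    medians = as.list(state$medians),
    maps = lapply(state$maps, function(m) list(values = m$values,
                                               scores = m$scores)),
    vocabs = state$vocabs, drop_list = state$drop_list,
    target_maps = if (is.null(state$target_maps)) NULL else
      lapply(state$target_maps, function(m) list(values = m$values,
                                                 scores = m$scores)),
    design_cols = state$design_cols)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_preprocess
#' @export
read_preprocess <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_map <- function(m) structure(list(values = as.numeric(m$values),
                                       scores = as.numeric(m$scores)),
                                  class = "gauss_rank_map")
  structure(list(numeric_cols = p$numeric_cols, discrete_cols = p$discrete_cols,
                 medians = unlist(p$medians), maps = lapply(p$maps, as_map),
                 vocabs = p$vocabs, drop_list = p$drop_list,
                 target_maps = if (is.null(p$target_maps)) NULL else
                   lapply(p$target_maps, as_map),
                 design_cols = p$design_cols),
            class = "l2c_preprocess")
}
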