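#' Gate member models by TSS
#'
#' Keeps models whose evaluation TSS is at or above \code{tss_min}
#' (boundary inclusive), preserving order. An empty result is legal here;
#' \code{\link{combine_members}} raises on it.
#'
#' @param models_with_eval list of entries each carrying \code{$eval$tss}
#' @param tss_min gate (default 0.6)
#' @return the passing subset of the list
#' @export
gate_members <- function(models_with_eval, tss_min = 0.6) {
  if (tss_min > 1) stop("tss_min above 1 can never be met")
  keep <- vapply(models_with_eval, function(m) {
    tss <- if (!is.null(m$eval)) m$eval$tss else m$tss
    !is.na(tss) && tss >= tss_min
  }, logical(1))
  models_with_eval[keep]
}

#' Combine member suitability maps into an ensemble map
#'
#' Five methods: cell-wise \code{median}; \code{mean}; \code{weighted_mean}
#' with per-member TSS weights normalized to sum 1;
#' \code{committee_average} = mean of member binary maps, each binarized at
#' its own maxSSS threshold; and \code{pca} = first principal component of
#' the cell x member matrix, sign-aligned to correlate positively with the
#' mean map and min-max rescaled to [0, 1]. Cells missing in any member
#' propagate as missing.
#'
#' @param member_maps list of co-registered \code{grid_raster} suitability
#'   maps (or numeric vectors)
#' @param method one of "median", "mean", "weighted_mean",
#'   "committee_average", "pca"
#' @param weights per-member TSS (required for weighted_mean; > 0)
#' @param thresholds per-member maxSSS thresholds (required for
#'   committee_average)
#' @return ensemble map of the same type as the inputs, values in [0, 1]
#' @export
combine_members <- function(member_maps,
                            method = c("median", "mean", "weighted_mean",
                                       "committee_average", "pca"),
                            weights = NULL, thresholds = NULL) {
  method <- match.arg(method)
  if (!length(member_maps)) stop("no member maps to combine")
  is_raster <- inherits(member_maps[[1]], "grid_raster")
  m <- if (is_raster) {
    vapply(member_maps, function(r) as.vector(r$values),
           numeric(length(member_maps[[1]]$values)))
  } else {
    vapply(member_maps, as.numeric, numeric(length(member_maps[[1]])))
  }

  out <- switch(method,
    median = apply(m, 1, stats::median),
    mean = rowMeans(m),
    weighted_mean = {
      if (is.null(weights) || length(weights) != ncol(m))
        stop("weighted_mean needs one weight per member")
      if (any(weights <= 0)) stop("weights must be positive")
      as.numeric(m %*% (weights / sum(weights)))
    },
    committee_average = {
      if (is.null(thresholds) || length(thresholds) != ncol(m))
        stop("committee_average needs one threshold per member")
      rowMeans(vapply(seq_len(ncol(m)), function(j)
        as.numeric(m[, j] >= thresholds[j]), numeric(nrow(m))))
    },
    pca = {
      ok <- stats::complete.cases(m)
      if (ncol(m) == 1) {
        m[, 1]
      } else {
        sds <- apply(m[ok, , drop = FALSE], 2, stats::sd)
        if (all(sds == 0) || sum(ok) < 2) {
          rowMeans(m) # degenerate: identical/constant members
        } else {
          pc <- stats::prcomp(m[ok, , drop = FALSE], center = TRUE,
                              scale. = FALSE)
          s1 <- rep(NA_real_, nrow(m))
          s1[ok] <- pc$x[, 1]
          if (isTRUE(stats::cor(s1[ok], rowMeans(m)[ok]) < 0)) s1 <- -s1
          rng <- range(s1, na.rm = TRUE)
          if (diff(rng) == 0) rowMeans(m)
          else (s1 - rng[1]) / diff(rng)
        }
      }
    })
  out[!stats::complete.cases(m)] <- NA_real_
  out <- pmin(1, pmax(0, out))
  if (is_raster) rst_like(member_maps[[1]], out) else out
}

#' Select the best ensemble method by TSS then Sorensen
#'
#' Maximizes TSS; ties broken by higher Sorensen, then by the canonical
#' method order (median, mean, weighted_mean, committee_average, pca).
#'
#' @param candidates_with_eval named list (names = method) of entries
#'   carrying \code{$eval} with \code{tss} and \code{sorensen}
#' @return the name of the winning method
#' @export
choose_best_ensemble <- function(candidates_with_eval) {
  if (!length(candidates_with_eval)) stop("no ensemble candidates")
  order_pref <- c("median", "mean", "weighted_mean", "committee_average",
                  "pca")
  nm <- names(candidates_with_eval)
  tss <- vapply(candidates_with_eval, function(c) c$eval$tss, numeric(1))
  sor <- vapply(candidates_with_eval, function(c) c$eval$sorensen,
                numeric(1))
  pref <- match(nm, order_pref, nomatch = length(order_pref) + 1)
  nm[order(-tss, -sor, pref)][1]
}

#' Clamping mask: projection cells outside the training range
#'
#' For each cell, counts the retained predictors whose projected value
#' falls outside the per-layer training [min, max]. The mask is the count;
#' \code{\link{apply_mask}} with it removes every cell with a non-zero
#' count.
#'
#' @param projection_stack \code{raster_stack} of projected predictor
#'   layers
#' @param training_range named list (per layer) of c(min, max) recorded
#'   over the study area under the training scenario
#' @return \code{grid_raster} of per-cell exceedance counts
#' @export
clamping_mask <- function(projection_stack, training_range) {
  vars <- intersect(names(projection_stack), names(training_range))
  if (!length(vars)) stop("no layers shared with the training range")
  tmpl <- projection_stack[[vars[1]]]
  count <- numeric(length(tmpl$values))
  for (v in vars) {
    vals <- as.vector(projection_stack[[v]]$values)
    rng <- training_range[[v]]
    count <- count + (!is.na(vals) & (vals < rng[1] | vals > rng[2]))
  }
  rst_like(tmpl, count)
}

#' Uncertainty mask: cells at or above an uncertainty quantile
#'
#' Masks the cells whose per-cell uncertainty is equal to or higher than
#' the \code{quantile} empirical quantile over data cells (about the top
#' 10 percent at the 0.90 default; ties at the quantile are included). A
#' constant uncertainty map masks everything, with a warning.
#'
#' @param uncertainty_map \code{grid_raster} of per-cell uncertainty
#' @param quantile quantile in (0, 1] (default 0.90)
#' @return \code{grid_raster} mask of 0/1 (1 = masked), NA where no data
#' @export
uncertainty_mask <- function(uncertainty_map, quantile = 0.90) {
  u <- as.vector(uncertainty_map$values)
  ok <- !is.na(u)
  if (!any(ok)) stop("uncertainty map has no data cells")
  q <- stats::quantile(u[ok], probs = quantile, type = 7, names = FALSE)
  if (max(u[ok]) == min(u[ok]))
    warning("constant uncertainty: every cell is at the quantile, all masked")
  m <- rep(NA_real_, length(u))
  m[ok] <- as.numeric(u[ok] >= q)
  rst_like(uncertainty_map, m)
}

#' Apply a mask to a suitability map
#'
#' Sets suitability to missing wherever the mask is non-zero (clamping
#' count > 0, or uncertainty flag = 1). Missing mask cells propagate as
#' missing.
#' @param suitability \code{grid_raster}
#' @param mask \code{grid_raster} of counts/flags
#' @return masked \code{grid_raster}
#' @export
apply_mask <- function(suitability, mask) {
  stopifnot(same_grid(suitability, mask))
  v <- as.vector(suitability$values)
  m <- as.vector(mask$values)
  v[is.na(m) | m > 0] <- NA_real_
  rst_like(suitability, v)
}

#' Per-layer training ranges of a predictor stack
#' @param stack \code{raster_stack}
#' @param cells optional cell subset (study-area cells)
#' @return named list of c(min, max)
#' @export
training_range <- function(stack, cells = NULL) {
  lapply(stack, function(l) {
    v <- as.vector(l$values)
    if (!is.null(cells)) v <- v[cells]
    range(v, na.rm = TRUE)
  })
}
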