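#' Build generalized LN models at one of four pooling levels
#'
#' Collapses the per-condition LN fits into generalized models selectable a
#' priori:
#' \describe{
#'   \item{M}{one model per variant: activation data are pooled as
#'     `g(a)/w` across all noise regimes, weights and working points and a
#'     single scaled spline `gbar` is fitted (used as `w * gbar(a)`); kernel
#'     parameters are per-parameter medians over all conditions.}
#'   \item{MN}{as M, but pooled per (variant, noise regime).}
#'   \item{MNW}{per (variant, noise, weight): the original per-condition
#'     activation spline, kernel parameters the medians over working points
#'     `(a0, a1)`.}
#'   \item{MNWS}{per (variant, noise, weight): the original activation
#'     spline and the single working point's filter that achieved the
#'     highest stepped-Poisson fit quality.}
#' }
#'
#' @param fits data frame of filter fits with columns `model`, `noise`, `w`,
#'   `a0`, `a1`, `gamma1`, `gamma2`, `f_c1`, `f_c2`, `delta`.
#' @param activations data frame of activation measurements with columns
#'   `model`, `noise`, `w`, `a0`, `r0` (knot-level rows).
#' @param level `"M"`, `"MN"`, `"MNW"` or `"MNWS"`.
#' @param stepped_results fit-quality records from [stepped_poisson_test()]
#'   (required for `"MNWS"`).
#' @return object of class `generalized_model_set`; concrete models are
#'   materialized with [generalized_ln_model()].
#' @export
generalize <- function(fits, activations, level = c("M", "MN", "MNW", "MNWS"),
                       stepped_results = NULL) {
  level <- match.arg(level)
  if (level == "MNWS" && is.null(stepped_results))
    stopf("MNWS generalization requires stepped_results")
  par_cols <- c("f_c1", "f_c2", "gamma1", "gamma2", "delta")
  stopifnot(all(c("model", "noise", "w", par_cols) %in% names(fits)))

  key_cols <- switch(level, M = "model", MN = c("model", "noise"),
                     MNW = c("model", "noise", "w"),
                     MNWS = c("model", "noise", "w"))
  keys <- unique(fits[key_cols])
  rownames(keys) <- NULL
  entries <- lapply(seq_len(nrow(keys)), function(i) {
    key <- keys[i, , drop = FALSE]
    sel <- rep(TRUE, nrow(fits))
    for (kc in key_cols) sel <- sel & fits[[kc]] == key[[kc]]
    ent <- as.list(key)
    if (level == "MNWS") {
      sr <- stepped_results
      ssel <- sr$model == key$model & sr$noise == key$noise & sr$w == key$w &
        sr$valid & is.finite(sr$er)
      if (!any(ssel)) return(NULL)
      best <- sr[ssel, ][which.max(sr$er[ssel]), ]
      fsel <- sel & fits$a0 == best$a0 & fits$a1 == best$a1
      if (!any(fsel)) return(NULL)
      ent$filter <- as.list(fits[which(fsel)[1], par_cols])
    } else {
      ent$filter <- as.list(vapply(par_cols, function(pc)
        stats::median(fits[[pc]][sel]), 0))
    }
    if (level %in% c("M", "MN")) {
      asel <- activations$model == key$model
      if (level == "MN") asel <- asel & activations$noise == key$noise
      ad <- activations[asel, ]
      scaled <- ad$r0 / ad$w
      knots <- sort(unique(ad$a0))
      vals <- vapply(knots, function(a) mean(scaled[ad$a0 == a]), 0)
      ent$g_scaled <- list(a0 = knots, value = vals)
    }
    ent
  })
  entries <- Filter(Negate(is.null), entries)
  structure(list(level = level, entries = entries,
                 activations = if (level %in% c("MNW", "MNWS"))
                   activations else NULL),
            class = "generalized_model_set")
}

#' Materialize a generalized LN model for a concrete condition
#'
#' @param gset a [generalize()] result.
#' @param model variant label.
#' @param noise noise-regime name.
#' @param w synaptic weight.
#' @return an [ln_model()], or `NULL` when the set has no entry for the key.
#' @export
generalized_ln_model <- function(gset, model, noise, w) {
  stopifnot(inherits(gset, "generalized_model_set"))
  lv <- gset$level
  ent <- NULL
  for (e in gset$entries) {
    if (e$model != model) next
    if (lv %in% c("MN", "MNW", "MNWS") && e$noise != noise) next
    if (lv %in% c("MNW", "MNWS") && e$w != w) next
    ent <- e
    break
  }
  if (is.null(ent)) return(NULL)
  act <- if (lv %in% c("M", "MN")) {
    activation_function(ent$g_scaled$a0, w * ent$g_scaled$value,
                        metadata = list(model = model, level = lv, w = w))
  } else {
    ad <- gset$activations
    asel <- ad$model == model & ad$noise == noise & ad$w == w
    if (!any(asel)) return(NULL)
    ad <- ad[asel, ]
    ord <- order(ad$a0)
    activation_function(ad$a0[ord], ad$r0[ord],
                        metadata = list(model = model, noise = noise, w = w))
  }
  fp <- ent$filter
  sw <- swap_filter_branches(fp$gamma1, fp$gamma2, fp$f_c1, fp$f_c2, fp$delta)
  ln_model(act, filter_params(sw$gamma1, sw$gamma2, sw$f_c1, sw$f_c2,
                              sw$delta),
           provenance = list(level = lv, model = model, noise = noise, w = w))
}

#' Group model variants by clustering fitted filter parameters
#'
#' Runs k-means on the standardized 5-dimensional kernel parameter vectors
#' `(gamma1, gamma2, f_c1, f_c2, delta)` of all fits (characteristic
#' frequencies on a log scale by default), counts how often each model
#' variant lands in each cluster, and assigns each variant to its plurality
#' cluster (ties broken deterministically: larger cluster first, then lower
#' cluster index). Every cluster that receives at least one variant becomes
#' a model group, reported with the median parameters over its members'
#' fits.
#'
#' @param fits data frame with columns `model`, `gamma1`, `gamma2`, `f_c1`,
#'   `f_c2`, `delta` (one row per fitted condition).
#' @param k number of clusters (default 7).
#' @param n_init number of random initializations (default 100).
#' @param seed optional seed.
#' @param log_freq cluster `log10(f_c)` instead of `f_c`.
#' @return list with `groups` (data frame: group id, member models, median
#'   parameters), `counts` (model x cluster matrix; row sums equal each
#'   model's number of fits), `assignment` (named vector model -> group) and
#'   the fitted `kmeans` object.
#' @export
cluster_models <- function(fits, k = 7, n_init = 100, seed = NULL,
                           log_freq = TRUE) {
  par_cols <- c("gamma1", "gamma2", "f_c1", "f_c2", "delta")
  stopifnot(all(c("model", par_cols) %in% names(fits)))
  X <- as.matrix(fits[par_cols])
  if (log_freq) {
    X[, "f_c1"] <- log10(X[, "f_c1"])
    X[, "f_c2"] <- log10(X[, "f_c2"])
  }
  if (nrow(X) < k)
    stopf("need at least k = %d parameter sets, got %d", k, nrow(X))
  Xs <- scale(X)
  Xs[, apply(Xs, 2, function(col) !all(is.finite(col)))] <- 0
  n_distinct <- nrow(unique(Xs))
  if (n_distinct < k) {
    # degenerate: fewer distinct parameter sets than clusters; cluster the
    # distinct values themselves (identical fits share a cluster)
    uq <- unique(Xs)
    keys <- apply(Xs, 1, paste, collapse = "\r")
    idx <- match(keys, apply(uq, 1, paste, collapse = "\r"))
    km <- list(cluster = idx,
               size = c(tabulate(idx, n_distinct), rep(0L, k - n_distinct)),
               centers = uq)
  } else {
    km <- with_seed(seed, stats::kmeans(Xs, centers = k, nstart = n_init,
                                        iter.max = 100))
  }
  models <- sort(unique(fits$model))
  counts <- matrix(0L, nrow = length(models), ncol = k,
                   dimnames = list(models, seq_len(k)))
  tab <- table(fits$model, km$cluster)
  counts[rownames(tab), colnames(tab)] <- tab
  sizes <- km$size
  assign_one <- function(mrow) {
    best <- which(mrow == max(mrow))
    if (length(best) > 1L) best <- best[order(-sizes[best], best)][1L]
    best
  }
  cluster_of <- apply(counts, 1, assign_one)
  occupied <- sort(unique(cluster_of))
  groups <- lapply(seq_along(occupied), function(gi) {
    cl <- occupied[gi]
    members <- models[cluster_of == cl]
    sel <- fits$model %in% members
    med <- vapply(par_cols, function(pc) stats::median(fits[[pc]][sel]), 0)
    data.frame(group = gi, cluster = cl,
               models = paste(members, collapse = ","),
               t(med))
  })
  assignment <- match(cluster_of, occupied)
  names(assignment) <- models
  list(groups = do.call(rbind, groups), counts = counts,
       assignment = assignment, kmeans = km)
}
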