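# Morphospace construction and disparity analyses: Gower distances for
# mixed-type traits, PCA / PCoA ordination, per-clade disparity, rarefied
# disparity with Bhattacharyya overlap, and disparity-through-time against
# a Brownian-motion null (MDI).

#' Gower distance for mixed-type trait tables
#'
#' `d(i, j)` is the mean, over the traits comparable for the pair (both
#' non-missing), of the per-trait dissimilarity: `|x - y| / range` for
#' continuous and ordinal traits, and 0/1 mismatch for binary and nominal
#' traits. Distances lie in [0, 1]; missing values are excluded pairwise.
#'
#' @param table data.frame (species x traits), rownames = species.
#' @param types character vector over columns, each one of `"cont"`,
#'   `"ord"`, `"bin"`, `"nom"`. Defaults to `"cont"` for numeric columns and
#'   `"nom"` otherwise.
#' @return symmetric `dist`-convertible matrix with zero diagonal.
#' @export
gower_distance <- function(table, types = NULL) {
  n <- nrow(table); p <- ncol(table)
  if (is.null(types))
    types <- ifelse(vapply(table, is.numeric, logical(1)), "cont", "nom")
  stopifnot(length(types) == p, all(types %in% c("cont", "ord", "bin", "nom")))
  contrib <- array(NA_real_, c(n, n, p))
  for (k in seq_len(p)) {
    x <- table[[k]]
    if (types[k] %in% c("cont", "ord")) {
      x <- as.numeric(x)
      rng <- diff(range(x, na.rm = TRUE))
      d <- abs(outer(x, x, "-"))
      d <- if (rng > 0) d / rng else d * 0
    } else {
      x <- as.character(x)
      d <- 1 - outer(x, x, "==") * 1
    }
    miss <- is.na(x)
    d[miss, ] <- NA; d[, miss] <- NA
    contrib[, , k] <- d
  }
  D <- apply(contrib, c(1, 2), mean, na.rm = TRUE)
  if (any(is.nan(D)))
    stop("species pair with zero comparable traits")
  dimnames(D) <- list(rownames(table), rownames(table))
  diag(D) <- 0
  D
}

#' Ordinate species into a morphospace
#'
#' PCA is the eigendecomposition of centered, scaled continuous data
#' (`prcomp(scale. = TRUE)`); PCoA is classical scaling of the
#' double-centered `-d^2/2` matrix, with the Cailliez constant added when
#' negative eigenvalues exceed tolerance. Scores are returned for all
#' positive-eigenvalue axes, with per-axis variance explained.
#'
#' @param x complete continuous data.frame/matrix (PCA) or a symmetric
#'   distance matrix (PCoA).
#' @param method `"PCA"` or `"PCoA"`.
#' @param correction for PCoA: `"none"` or `"cailliez"` (applied only when
#'   needed).
#' @return object of class `morphospace`: `scores` (species x axes),
#'   `var_explained` (proportions, nonincreasing), `method`, `correction`.
#' @export
ordinate <- function(x, method = c("PCA", "PCoA"),
                     correction = c("cailliez", "none")) {
  method <- match.arg(method); correction <- match.arg(correction)
  if (method == "PCA") {
    x <- as.matrix(x)
    if (anyNA(x)) stop("PCA requires a complete table")
    if (nrow(x) < 3) stop("fewer than 3 species")
    pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
    keep <- pc$sdev^2 > 1e-12 * pc$sdev[1]^2
    scores <- pc$x[, keep, drop = FALSE]
    ve <- pc$sdev^2 / sum(pc$sdev^2)
    out <- list(scores = scores, var_explained = ve[keep], method = "PCA",
                correction = "none")
  } else {
    D <- as.matrix(x)
    if (nrow(D) < 3) stop("fewer than 3 species")
    corr_used <- "none"
    pco <- ape::pcoa(stats::as.dist(D))
    if (min(pco$values$Eigenvalues) < -1e-8 * max(pco$values$Eigenvalues) &&
        correction == "cailliez") {
      pco <- ape::pcoa(stats::as.dist(D), correction = "cailliez")
      corr_used <- "cailliez"
    }
    vex <- if (corr_used == "cailliez" && !is.null(pco$vectors.cor))
      pco$vectors.cor else pco$vectors
    ev_col <- if (corr_used == "cailliez" &&
                  "Corr_eig" %in% names(pco$values)) "Corr_eig"
              else "Eigenvalues"
    ev <- pco$values[[ev_col]]
    keep <- which(ev > 1e-8 * max(ev))
    keep <- keep[keep <= ncol(vex)]
    scores <- vex[, keep, drop = FALSE]
    rownames(scores) <- rownames(D)
    ve <- ev[keep] / sum(ev[keep])
    out <- list(scores = scores, var_explained = ve, method = "PCoA",
                correction = corr_used)
  }
  colnames(out$scores) <- paste0("PC", seq_len(ncol(out$scores)))
  structure(out, class = "morphospace")
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("morphospace (%s%s): %d species x %d axes; axis 1-3 var: %s\n",
              x$method,
              if (x$correction != "none") paste0(", ", x$correction) else "",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%",
                            100 * utils::head(x$var_explained, 3)),
                    collapse = " ")))
  invisible(x)
}

#' Per-clade disparity: mean squared pairwise distance
#'
#' Mean over all unordered pairs of the squared Euclidean distance between
#' the members' ordination coordinates. Algebraically equal to twice the
#' sum over axes of the sample variance (denominator n - 1).
#'
#' @param scores species x axes matrix (rownames = species) or numeric
#'   vector.
#' @param members species in the clade (>= 2), default all.
#' @return scalar disparity.
#' @export
clade_disparity <- function(scores, members = NULL) {
  if (is.null(dim(scores))) scores <- cbind(scores)
  if (!is.null(members)) {
    miss <- setdiff(members, rownames(scores))
    if (length(miss)) stop("members missing from scores: ",
                           paste(miss, collapse = ", "))
    scores <- scores[members, , drop = FALSE]
  }
  n <- nrow(scores)
  if (n < 2) stop("need >= 2 members")
  2 * sum(apply(scores, 2, stats::var))
}

#' Bhattacharyya coefficient between two samples
#'
#' Overlap `sum_bins sqrt(p_i q_i)` of the two samples' histograms on a
#' shared binning (Sturges' rule on the pooled sample); 1 for identical
#' distributions, 0 for disjoint support.
#'
#' @param x,y numeric samples.
#' @param breaks optional shared break points.
#' @return coefficient in [0, 1].
#' @export
bhattacharyya_coef <- function(x, y, breaks = NULL) {
  if (is.null(breaks)) {
    pooled <- c(x, y)
    nb <- max(1, ceiling(log2(length(pooled)) + 1))  # Sturges
    rng <- range(pooled)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = nb + 1)
  }
  p <- graphics::hist(pmin(pmax(x, breaks[1]), breaks[length(breaks)]),
                      breaks = breaks, plot = FALSE)$counts
  q <- graphics::hist(pmin(pmax(y, breaks[1]), breaks[length(breaks)]),
                      breaks = breaks, plot = FALSE)$counts
  sum(sqrt((p / sum(p)) * (q / sum(q))))
}

#' Rarefied per-clade disparity with Bhattacharyya comparisons
#'
#' Clades differing in size are compared on equal footing by repeatedly
#' subsampling each clade to `n` species and recomputing disparity; the
#' pairwise Bhattacharyya coefficient of the rarefied disparity
#' distributions (shared Sturges binning on the pooled pair) measures
#' overlap, with clades conventionally flagged distinct when BC < 0.05.
#'
#' @param scores species x axes matrix.
#' @param clades list of [clade_def()] objects (each with >= `n` members).
#' @param n rarefied clade size (default 4).
#' @param reps subsamples per clade (default 100).
#' @param seed RNG seed.
#' @param bc_threshold distinctness threshold on BC (default 0.05).
#' @return list with `distributions` (reps x clades matrix), `pairwise`
#'   (data.frame: clade_a, clade_b, bc, distinct).
#' @export
rarefied_disparity <- function(scores, clades, n = 4, reps = 100, seed = 1,
                               bc_threshold = 0.05) {
  names(clades) <- vapply(clades, function(cl) cl$name, character(1))
  for (cl in clades)
    if (length(cl$tips) < n)
      stop("clade '", cl$name, "' smaller than rarefaction size ", n)
  dist_mat <- with_seed(seed, {
    vapply(clades, function(cl) {
      vapply(seq_len(reps), function(i)
        clade_disparity(scores, sample(cl$tips, n)), numeric(1))
    }, numeric(reps))
  })
  cmb <- utils::combn(names(clades), 2)
  pw <- data.frame(clade_a = cmb[1, ], clade_b = cmb[2, ],
                   bc = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(cmb)))
    pw$bc[i] <- bhattacharyya_coef(dist_mat[, cmb[1, i]],
                                   dist_mat[, cmb[2, i]])
  pw$distinct <- pw$bc < bc_threshold
  list(distributions = dist_mat, pairwise = pw)
}

# mean relative subclade disparity at given ages; `tipsets` is the list of
# descendant-tip index vectors per node, `disp_all` the full-tree disparity
dtt_curve <- function(tree, scores, ages_eval) {
  ntip <- ape::Ntip(tree)
  ages <- node_ages(tree)
  disp_all <- clade_disparity(scores)
  a_parent <- ages[tree$edge[, 1]]
  a_child <- ages[tree$edge[, 2]]
  sub_disp <- numeric(ntip + tree$Nnode)  # disparity of each node's tip set
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    labs <- tree$tip.label[tips_under(tree, v)]
    sub_disp[v] <- clade_disparity(scores, labs)
  }
  vapply(ages_eval, function(t0) {
    if (t0 >= max(ages)) return(1)
    cross <- which(a_parent > t0 & a_child <= t0)
    vals <- vapply(cross, function(e) {
      v <- tree$edge[e, 2]
      if (v <= ntip) 0 else sub_disp[v]
    }, numeric(1))
    mean(vals) / disp_all
  }, numeric(1))
}

#' Disparity-through-time with a Brownian-motion null and MDI
#'
#' At each internal-node age (or supplied bin edges), the relative disparity
#' is the mean, over the lineages crossing that age, of the disparity of the
#' lineage's descendant tips divided by the disparity of all tips (1 at the
#' root by construction). The null is the same computation on multivariate
#' BM data simulated on the tree with per-axis rates estimated from the
#' observed data by the contrasts estimator. MDI is the signed area
#' (trapezoid, over relative time from root to present) between the observed
#' curve and the pointwise null median; the reported two-sided p-value is
#' the add-one-corrected rank of the observed MDI among the null MDIs.
#'
#' @param tree ultrametric `phylo` (>= 3 tips).
#' @param scores species x axes matrix (complete, rownames = species).
#' @param sims number of BM null simulations (>= 2; 1000 for a
#'   publication-grade envelope).
#' @param seed RNG seed.
#' @param ages_eval optional evaluation ages (Ma, descending); defaults to
#'   all internal-node ages.
#' @param envelope envelope coverage (default 0.95).
#' @return object of class `dtt_result`: `ages`, `observed`, `null_median`,
#'   `null_lower`, `null_upper`, `null_curves`, `mdi`, `null_mdi`,
#'   `p_value`, `inside_envelope` (fraction of observed points within the
#'   pointwise envelope).
#' @export
dtt <- function(tree, scores, sims = 1000, seed = 1, ages_eval = NULL,
                envelope = 0.95) {
  assert_time_tree(tree, bifurcating = FALSE)
  if (sims < 2) stop("sims must be >= 2")
  if (is.null(dim(scores))) scores <- cbind(scores)
  if (anyNA(scores)) stop("scores must be complete")
  scores <- scores[tree$tip.label, , drop = FALSE]
  ages <- node_ages(tree)
  ntip <- ape::Ntip(tree)
  if (is.null(ages_eval))
    ages_eval <- sort(ages[(ntip + 1L):length(ages)], decreasing = TRUE)
  obs <- dtt_curve(tree, scores, ages_eval)
  # per-axis BM rates via phylogenetically independent contrasts
  rates <- apply(scores, 2, function(y) mean(ape::pic(y, tree)^2))
  seeds <- spawn_seeds(seed, sims)
  null_curves <- vapply(seq_len(sims), function(i) {
    sim <- simulate_traits_bm(tree, 1, dims = ncol(scores),
                              seed = seeds[i])$traits
    sim <- sweep(sim, 2, sqrt(rates), "*")
    dtt_curve(tree, sim[tree$tip.label, , drop = FALSE], ages_eval)
  }, numeric(length(ages_eval)))
  null_med <- apply(null_curves, 1, stats::median)
  alpha <- (1 - envelope) / 2
  null_lo <- apply(null_curves, 1, stats::quantile, probs = alpha)
  null_hi <- apply(null_curves, 1, stats::quantile, probs = 1 - alpha)
  T <- max(ages)
  rel_t <- (T - ages_eval) / T  # 0 at root, 1 at present
  mdi_of <- function(curve) {
    d <- curve - null_med
    sum(diff(rel_t) * (utils::head(d, -1) + utils::tail(d, -1)) / 2)
  }
  mdi <- mdi_of(obs)
  null_mdi <- apply(null_curves, 2, mdi_of)
  p <- min(1, (1 + 2 * min(sum(null_mdi >= mdi), sum(null_mdi <= mdi))) /
             (sims + 1))
  structure(list(ages = ages_eval, observed = obs, null_median = null_med,
                 null_lower = null_lo, null_upper = null_hi,
                 null_curves = null_curves, mdi = mdi, null_mdi = null_mdi,
                 p_value = p,
                 inside_envelope = mean(obs >= null_lo & obs <= null_hi)),
            class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat(sprintf(
    "dtt_result: %d time points, MDI=%.4f (p=%.3f), %.0f%% of curve inside envelope\n",
    length(x$ages), x$mdi, x$p_value, 100 * x$inside_envelope))
  invisible(x)
}
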