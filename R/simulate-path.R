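#' Simulate a phylogenetic path-analysis dataset with known truth
#'
#' Generates the standard variable set {BG, climR, vegR, florR, SR} on the
#' tips of a tree under a causal DAG: variables are built in topological
#' order as `sum(coef * standardized parent) + noise`, with the noise drawn
#' from `N(0, sigma^2 [lambda V* + (1 - lambda) I])` (V* = Brownian
#' covariance scaled to unit diagonal), so residuals carry Pagel's-lambda
#' phylogenetic signal. `BG` is produced by thresholding its latent
#' phylogenetic variable at the median (guaranteeing both classes) and
#' enters children as a standardized 0/1 covariate.
#'
#' @param tree ultrametric `phylo`.
#' @param model a [causal_model()] (acyclic; coefficients required for
#'   every edge).
#' @param coefs named numeric vector of path coefficients, names `"A->B"`.
#' @param lambda residual Pagel's lambda, scalar or named per variable.
#' @param sigma residual sd, scalar or named per variable.
#' @param seed RNG seed.
#' @return `list(data, truth)`; `data` is a data.frame (rownames = species)
#'   with BG in {0,1} and the other variables continuous.
#' @export
make_ppa_dataset <- function(tree, model, coefs, lambda = 0.5, sigma = 1,
                             seed) {
  edges <- model$edges
  enames <- if (nrow(edges)) paste0(edges[, 1], "->", edges[, 2]) else
    character(0)
  miss <- setdiff(enames, names(coefs))
  if (length(miss)) stop("missing coefficient(s): ",
                         paste(miss, collapse = ", "))
  vars <- topo_order(model)
  get_par <- function(par, v, default) {
    if (length(par) == 1 && is.null(names(par))) return(par)
    par[[v]] %||% default
  }
  n <- ape::Ntip(tree)
  V <- bm_vcv(tree)[tree$tip.label, tree$tip.label]
  V <- V / mean(diag(V))
  with_seed(seed, {
    noise_for <- function(v) {
      lam <- get_par(lambda, v, 0.5); sg <- get_par(sigma, v, 1)
      S <- lam * V + (1 - lam) * diag(n)
      drop(crossprod(chol(S), stats::rnorm(n))) * sg
    }
    out <- list()
    for (v in vars) {
      pa <- parents_of(model, v)
      base <- rep(0, n)
      for (p in pa) {
        pv <- out[[p]]
        pv <- if (stats::sd(pv) > 0) as.numeric(scale(pv)) else pv * 0
        base <- base + coefs[[paste0(p, "->", v)]] * pv
      }
      val <- base + noise_for(v)
      if (v == "BG") val <- as.numeric(val > stats::median(val))
      out[[v]] <- val
    }
    data <- as.data.frame(out)[, model$vertices, drop = FALSE]
    rownames(data) <- tree$tip.label
    list(data = data,
         truth = list(model = model$name, coefs = coefs, lambda = lambda,
                      sigma = sigma, seed = seed))
  })
}
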