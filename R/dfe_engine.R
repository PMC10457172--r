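#' Two-epoch demography
#'
#' Nuisance demographic model absorbing SFS distortions: an ancestral
#' population at equilibrium (effective size rescaled to `ne1`, the
#' convention of SFS-based DFE tools) changes to relative size `nu = N2/N1`
#' and stays there for `t2` generations before sampling. `t2 = 0` or
#' `nu = 1` is the stationary single-epoch model.
#'
#' @param nu post-change size relative to ancestral (> 0).
#' @param t2 duration of the post-change epoch, in generations of the
#'   rescaled model (>= 0).
#' @param ne1 rescaled ancestral diploid effective size (default 100).
#' @return object of class `demography_fit`. Fitted objects (see
#'   [fit_neutral()]) additionally carry `lambda4`, `lambda_site`, `L4`,
#'   `logL` and `converged`.
#' @export
demography <- function(nu = 1, t2 = 0, ne1 = 100) {
  if (nu <= 0) stop("nu must be > 0")
  if (t2 < 0) stop("t2 must be >= 0")
  structure(list(nu = nu, t2 = t2, ne1 = ne1, lambda4 = NA_real_,
                 lambda_site = NA_real_, L4 = NA_real_, logL = NA_real_,
                 converged = NA), class = "demography_fit")
}

#' @export
print.demography_fit <- function(x, ...) {
  cat(sprintf("two-epoch demography: N2/N1 = %.4g, t2 = %.4g generations (Ne1 = %g)\n",
              x$nu, x$t2, x$ne1))
  if (is.finite(x$logL))
    cat(sprintf("  logL = %.3f, lambda4 = %.4g (%s)\n", x$logL, x$lambda4,
                ifelse(isTRUE(x$converged), "converged", "not converged")))
  invisible(x)
}

## ---- quadrature over population allele frequency -------------------------

# composite 8-point Gauss-Legendre nodes on (1e-9, 1): geometric panels over
# the boundary layer near 0 (selection pushes mass there), linear above 0.1
gl_nodes <- function() {
  if (!is.null(.hapsel_cache$nodes)) return(.hapsel_cache$nodes)
  gx <- c(-0.9602898564975363, -0.7966664774136267, -0.5255324099163290,
          -0.1834346424956498, 0.1834346424956498, 0.5255324099163290,
          0.7966664774136267, 0.9602898564975363)
  gw <- c(0.1012285362903763, 0.2223810344533745, 0.3137066458778873,
          0.3626837833783620, 0.3626837833783620, 0.3137066458778873,
          0.2223810344533745, 0.1012285362903763)
  brk <- c(exp(seq(log(1e-9), log(0.1), length.out = 49)),
           seq(0.1, 1, length.out = 31)[-1])
  a <- brk[-length(brk)]; b <- brk[-1]
  x <- as.vector(outer(gx, (b - a) / 2) + rep((a + b) / 2, each = length(gx)))
  w <- as.vector(outer(gw, (b - a) / 2))
  .hapsel_cache$nodes <- list(x = x, w = w)
  .hapsel_cache$nodes
}

# stationary density of segregating sites under genic selection
# (Poisson-random-field form), theta = 1 scale; gam = Ne * s (<= 0 deleterious)
prf_density <- function(x, gam) {
  if (abs(gam) < 1e-9) return(1 / x)
  if (gam < 0) {       # deleterious: rearrange so every exponent is negative
    a <- -2 * gam
    exp(-a * x) * (-expm1(-a * (1 - x))) / (-expm1(-a)) / (x * (1 - x))
  } else {             # advantageous: exponents already negative
    (-expm1(-2 * gam * (1 - x))) / (-expm1(-2 * gam)) / (x * (1 - x))
  }
}

# cache: binomial sampling kernel to n alleles evaluated at the nodes
binom_kernel <- function(n) {
  key <- paste0("D", n)
  if (!is.null(.hapsel_cache[[key]])) return(.hapsel_cache[[key]])
  nod <- gl_nodes()
  D <- vapply(nod$x, function(x) dbinom(1:(n - 1), n, x),
              numeric(n - 1))              # (n-1) x Q
  .hapsel_cache[[key]] <- D
  D
}

# expected unfolded sample SFS (bins 1..n-1, unit scale) at stationarity
eq_sample_sfs <- function(n, gam) {
  nod <- gl_nodes()
  as.vector(binom_kernel(n) %*% (nod$w * prf_density(nod$x, gam)))
}

fold_vector <- function(e, n) {
  nb <- floor(n / 2)
  vapply(seq_len(nb), function(i) if (i < n - i) e[i] + e[n - i] else e[i],
         numeric(1))
}

## ---- transient second epoch on a Wright-Fisher grid ----------------------

# deterministic allele-frequency change under additive selection
sel_shift <- function(p, s) {
  sigma <- s / 2
  q <- p * (1 + sigma) / (1 + p * sigma)
  pmin(pmax(q, 0), 1)
}

# WF transition among transient states 1..(size-1), column-stochastic block
wf_transient <- function(size, s) {
  key <- sprintf("W%d_%.12g", size, s)
  if (!is.null(.hapsel_cache[[key]])) return(.hapsel_cache[[key]])
  pp <- sel_shift((1:(size - 1)) / size, s)
  M <- vapply(pp, function(q) dbinom(1:(size - 1), size, q),
              numeric(size - 1))
  keys <- grep("^W", ls(.hapsel_cache), value = TRUE)
  if (length(keys) > 50)                      # bound cache memory
    rm(list = keys[seq_len(10)], envir = .hapsel_cache)
  .hapsel_cache[[key]] <- M
  M
}

# discretisation of the stationary density onto a grid of `size` copies
grid_kernel <- function(size) {
  key <- sprintf("B%d", size)
  if (!is.null(.hapsel_cache[[key]])) return(.hapsel_cache[[key]])
  nod <- gl_nodes()
  B <- vapply(nod$x, function(x) dbinom(1:(size - 1), size, x),
              numeric(size - 1))           # (size-1) x Q
  keys <- grep("^B", ls(.hapsel_cache), value = TRUE)
  if (length(keys) > 60) rm(list = keys[1], envir = .hapsel_cache)
  .hapsel_cache[[key]] <- B
  B
}

# hypergeometric projection grid states -> n alleles (rows k = 1..n-1)
hyper_kernel <- function(size, n) {
  key <- sprintf("H%d_%d", size, n)
  if (!is.null(.hapsel_cache[[key]])) return(.hapsel_cache[[key]])
  j <- 1:(size - 1)
  H <- t(vapply(j, function(jj) dhyper(1:(n - 1), jj, size - jj, n),
                numeric(n - 1)))           # (size-1) x (n-1); transpose below
  .hapsel_cache[[key]] <- t(H)
  .hapsel_cache[[key]]
}

# expected unfolded sample SFS (bins 1..n-1, unit epoch-1 scale) for a
# two-epoch demography and selection coefficient s
expected_sample_sfs_unfolded <- function(demog, s, n) {
  stopifnot(inherits(demog, "demography_fit"))
  if (n < 2) stop("n must be >= 2")
  if (!is.finite(s)) stop("non-finite selection coefficient")
  nc1 <- 2L * demog$ne1
  gam1 <- demog$ne1 * s
  t2 <- round(demog$t2)
  if (t2 == 0 || abs(demog$nu - 1) < 1e-12)
    return(eq_sample_sfs(n, gam1))
  # snap the transient grid to multiples of 8 copies and the epoch duration
  # to a geometric ladder (~8% relative resolution), so likelihood searches
  # revisit cached expectations instead of rebuilding the transient solve
  nc2 <- max(8L, 8L * as.integer(round(demog$nu * nc1 / 8)))
  if (nc2 < n)
    stop("post-change population too small for the requested sample size")
  if (t2 > 16) t2 <- as.integer(round(exp(round(log(t2) / 0.08) * 0.08)))
  gam2 <- (nc2 / 2) * s
  if (t2 >= 2 * nc2)                            # effectively re-equilibrated
    return(demog$nu * eq_sample_sfs(n, gam2))
  ekey <- sprintf("E%d_%d_%.12g_%d", nc2, t2, s, n)
  hit <- .hapsel_cache[[ekey]]
  if (!is.null(hit)) return(hit)
  nod <- gl_nodes()
  B <- grid_kernel(nc2)
  psi_init <- as.vector(B %*% (nod$w * prf_density(nod$x, gam1)))
  psi_eq2 <- demog$nu * as.vector(B %*% (nod$w * prf_density(nod$x, gam2)))
  M <- wf_transient(nc2, s)
  v <- psi_init - psi_eq2
  for (g in seq_len(t2)) v <- as.vector(M %*% v)
  psi <- pmax(psi_eq2 + v, 0)
  res <- as.vector(hyper_kernel(nc2, n) %*% psi)
  if (length(grep("^E", ls(.hapsel_cache))) > 20000)
    rm(list = grep("^E", ls(.hapsel_cache), value = TRUE),
       envir = .hapsel_cache)
  .hapsel_cache[[ekey]] <- res
  res
}

#' Expected folded SFS under the two-epoch model with selection
#'
#' Expected site counts over folded bins `0..floor(n/2)` for a single
#' selection coefficient. The stationary epoch uses the closed-form
#' population-frequency density of the Poisson random field under genic
#' (additive) selection, integrated by composite Gauss-Legendre quadrature;
#' a post-change epoch is propagated on a discrete Wright-Fisher grid of
#' `2 * ne1 * nu` gene copies for `t2` generations and projected to `n`
#' alleles hypergeometrically. Bin 0 absorbs all non-segregating mass.
#'
#' @param demog a [demography()].
#' @param s selection coefficient of the derived allele (0 = neutral;
#'   negative = deleterious; additive, heterozygote effect `s/2`). The scaled
#'   strength is `gamma = ne1 * s` in the ancestral epoch.
#' @param n sample size in alleles (>= 2).
#' @param mut_scale mutational scale multiplying the unit-rate expectation
#'   (for neutral equilibrium data this equals `theta * L`).
#' @param total_sites total number of sites; when given, bin 0 is
#'   `total_sites` minus the expected segregating mass, otherwise 0.
#' @return named numeric vector of expected counts, bins `0..floor(n/2)`.
#' @export
#' @examples
#' e <- expected_folded_sfs(demography(), s = 0, n = 16)
#' e[-1] / e[2]   # proportional to folded 1/i + 1/(n-i)
expected_folded_sfs <- function(demog, s, n, mut_scale = 1,
                                total_sites = NULL) {
  e <- expected_sample_sfs_unfolded(demog, s, n)
  if (any(!is.finite(e))) stop("non-finite SFS expectation")
  seg <- mut_scale * fold_vector(e, n)
  bin0 <- if (is.null(total_sites)) 0 else max(total_sites - sum(seg), 0)
  setNames(c(bin0, seg), 0:floor(n / 2))
}
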