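#' Simulate a paired 0-fold / 4-fold folded SFS under a known DFE
#'
#' Draws Poisson counts around the model expectation of the DFE engine: the
#' 4-fold spectrum is neutral, the 0-fold spectrum integrates the expected
#' SFS over the ground-truth gamma DFE, both under the ground-truth two-epoch
#' demography. Bin 0 holds the invariant remainder of `L0` / `L4` sites.
#'
#' @param truth a [ground_truth()].
#' @param L0,L4 numbers of 0-fold and 4-fold sites (> 0).
#' @param n sample size in alleles (`2 <= n`).
#' @param seed seed of the Poisson draw.
#' @param theta per-site scaled mutation rate setting the segregating scale
#'   (default 0.005).
#' @param ne1 rescaled ancestral size of the engine.
#' @return list with `fsfs0` and `fsfs4` ([folded_sfs()] objects) and the
#'   expected vectors `expected0`, `expected4`.
#' @export
simulate_fsfs_pair <- function(truth, L0, L4, n, seed = 1, theta = 0.005,
                               ne1 = 100) {
  stopifnot(inherits(truth, "ground_truth"))
  if (L0 <= 0 || L4 <= 0) stop("L0 and L4 must be > 0")
  if (n < 2) stop("n must be >= 2")
  dm <- demography(nu = truth$N2_ratio, t2 = truth$t2, ne1 = ne1)
  e4 <- expected_folded_sfs(dm, s = 0, n = n, mut_scale = theta * L4,
                            total_sites = L4)
  grid <- default_nes_grid()
  PHI <- dfe_phi_matrix(dm, n, grid)
  w <- gamma_class_weights(truth$beta, truth$Es, grid / ne1)
  seg0 <- theta * L0 * as.vector(PHI %*% w)
  e0 <- setNames(c(max(L0 - sum(seg0), 0), seg0), 0:floor(n / 2))
  if (any(!is.finite(e0)) || any(!is.finite(e4)))
    stop("non-finite SFS expectation")
  with_seed(derive_seed(seed, 61), {
    b0 <- rpois(length(e0), e0)
    b4 <- rpois(length(e4), e4)
    list(fsfs0 = folded_sfs(n, b0, "0-fold", seed = seed),
         fsfs4 = folded_sfs(n, b4, "4-fold", seed = seed),
         expected0 = e0, expected4 = e4)
  })
}
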