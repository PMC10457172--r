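#' Fit the two-epoch demography to a neutral (4-fold) folded SFS
#'
#' Maximises the product of independent Poisson likelihoods over folded bins
#' (bin 0 included) of [expected_folded_sfs()] at `s = 0`, over the relative
#' post-change size `nu`, the epoch duration `t2` and the neutral mutational
#' scale. The mutational scale is profiled out in closed form (its Poisson
#' MLE is `S / sum(phi)` for unit-scale shape `phi`); the demographic pair
#' `(nu, t2)` is located on a coarse grid including the conventional
#' starting duration (`t2 = 50` generations) and polished by Nelder-Mead
#' from the best grid cells, so fits are deterministic.
#'
#' @param fsfs4 a [folded_sfs()] of putatively neutral sites.
#' @param init_t2 starting epoch duration in generations (default 50).
#' @param ne1 rescaled ancestral size (default 100).
#' @param nu_range allowed `N2/N1` (soft box, default `[0.1, 5]`).
#' @param t2_max largest epoch duration explored.
#' @param n_polish number of best grid cells polished by Nelder-Mead.
#' @param seed unused placeholder kept for interface stability.
#' @return a fitted [demography()] carrying `lambda4` (fitted neutral scale),
#'   `lambda_site` (= `lambda4 / L4`), `L4`, `logL` and `converged`.
#' @export
fit_neutral <- function(fsfs4, init_t2 = 50, ne1 = 100,
                        nu_range = c(0.1, 5), t2_max = 600,
                        n_polish = 3, seed = 1) {
  stopifnot(inherits(fsfs4, "folded_sfs"))
  obs <- fsfs4$bins
  n <- fsfs4$n
  L <- sum(obs)
  S <- sum(obs[-1])
  if (S == 0) {
    warning("no segregating sites: demography unidentifiable, returning equilibrium boundary fit")
    d <- demography(1, 0, ne1)
    d$lambda4 <- 0; d$lambda_site <- 0; d$L4 <- L
    d$logL <- sum(dpois(obs, c(L, rep(1e-12, length(obs) - 1)), log = TRUE))
    d$converged <- FALSE
    return(d)
  }
  lb <- log(nu_range)
  # profile likelihood: the Poisson MLE of the mutational scale given the
  # unit-scale segregating shape phi is exactly S / sum(phi), because the
  # folded bins (bin 0 included) sum to the fixed site total L
  # tiny parsimony tie-break: near-equilibrium data leave (nu, t2) on a
  # likelihood plateau, so an epsilon pull towards the stationary model makes
  # the argmax deterministic and keeps the transient grid small
  tiebreak <- function(nu, t2) 0.02 * abs(log(nu)) + 0.005 * log1p(t2)
  nll_cell <- function(nu, t2) {
    phi <- fold_vector(expected_sample_sfs_unfolded(demography(nu, t2, ne1),
                                                    0, n), n)
    lam <- S / sum(phi)
    e <- c(max(L - lam * sum(phi), 1e-9), lam * phi)
    list(nll = -sum(dpois(obs, pmax(e, 1e-12), log = TRUE)) +
           tiebreak(nu, t2), lam = lam)
  }
  nu_grid <- exp(seq(lb[1], lb[2], length.out = 13))
  t2_grid <- c(0, 3, 6, 12, 25, init_t2, 100, 200, 400, t2_max)
  cells <- expand.grid(nu = nu_grid, t2 = t2_grid)
  cells$nll <- vapply(seq_len(nrow(cells)),
                      function(i) nll_cell(cells$nu[i], cells$t2[i])$nll,
                      numeric(1))
  cells <- cells[order(cells$nll), , drop = FALSE]
  obj <- function(p) {
    nu <- exp(min(max(p[1], lb[1]), lb[2]))
    t2 <- min(max(round(expm1(p[2])), 0), t2_max)
    pen <- 1e3 * (max(p[1] - lb[2], 0)^2 + max(lb[1] - p[1], 0)^2)
    nll_cell(nu, t2)$nll + pen
  }
  best <- NULL
  for (k in seq_len(min(n_polish, nrow(cells)))) {
    st <- c(log(cells$nu[k]), log1p(cells$t2[k]))
    f <- try(optim(st, obj, method = "Nelder-Mead",
                   control = list(maxit = 200, reltol = 1e-9)), silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best)) stop("neutral fit failed from every start")
  nu_hat <- exp(min(max(best$par[1], lb[1]), lb[2]))
  t2_hat <- min(max(round(expm1(best$par[2])), 0), t2_max)
  d <- demography(nu_hat, t2_hat, ne1)
  cell <- nll_cell(nu_hat, t2_hat)
  d$lambda4 <- cell$lam
  d$lambda_site <- d$lambda4 / L
  d$L4 <- L
  d$logL <- -(cell$nll - tiebreak(nu_hat, t2_hat))
  d$converged <- best$convergence == 0
  d
}

# geometric grid of scaled selection strengths spanning the visible range
default_nes_grid <- function(n_classes = 64, lo = 1e-4, hi = 1e4) {
  exp(seq(log(lo), log(hi), length.out = n_classes))
}

# expected folded segregating bins (unit scale) for each DFE quadrature class:
# column 1 is the neutral class, then one column per grid strength
dfe_phi_matrix <- function(demog, n, nes_grid) {
  s_grid <- -nes_grid / demog$ne1
  cols <- c(0, s_grid)
  vapply(cols, function(s)
    fold_vector(expected_sample_sfs_unfolded(demog, s, n), n),
    numeric(floor(n / 2)))
}

# gamma(shape beta, mean Es) probability mass over the quadrature classes;
# mass below the first edge goes to the neutral column, mass above the last
# edge stays in the last (effectively invisible) class
gamma_class_weights <- function(beta, Es, s_grid_abs) {
  if (!is.finite(Es) || Es < 1e-300 || !is.finite(beta) || beta <= 0)
    return(c(1, rep(0, length(s_grid_abs))))   # fully neutral limit
  if (!is.finite(Es / beta))                   # all mass beyond the grid top:
    return(c(rep(0, length(s_grid_abs)), 1))   # effectively invisible
  mid <- sqrt(s_grid_abs[-1] * s_grid_abs[-length(s_grid_abs)])
  edges <- c(0, mid, Inf)
  p <- diff(pgamma(edges, shape = beta, scale = Es / beta))
  # effects below half the smallest grid value are treated as fully neutral
  below <- pgamma(s_grid_abs[1] / 2, shape = beta, scale = Es / beta)
  c(below, p[1] - below, p[-1])
}

#' Fit a gamma DFE to a selected (0-fold) folded SFS
#'
#' With the demography fixed from [fit_neutral()], integrates the expected
#' folded SFS over a gamma distribution of deleterious effects (shape `beta`,
#' mean magnitude `Es`) via a geometric quadrature over scaled strengths
#' `Nes` in `[1e-4, 1e4]` (plus a neutral class for the sub-grid tail), and
#' maximises the Poisson likelihood over `(beta, Es)`. By default the 0-fold
#' mutational scale is tied to the fitted neutral per-site rate times the
#' number of 0-fold sites (`tie_scale = TRUE`), which makes the model
#' identifiable from folded data; `tie_scale = FALSE` frees it as a third
#' parameter.
#'
#' @param fsfs0 a [folded_sfs()] of selected sites.
#' @param demog fitted [demography()] from [fit_neutral()] (must carry
#'   `lambda_site` when `tie_scale = TRUE`).
#' @param init_s starting mean effect (sign ignored; default -0.1).
#' @param init_beta starting shape (default 0.5).
#' @param tie_scale tie the 0-fold scale to the neutral per-site rate.
#' @param mu_ratio 0-fold over 4-fold per-site mutation rate (default 1).
#' @param nes_grid quadrature grid of scaled strengths.
#' @param n_restarts,seed jittered restarts and their fixed seed.
#' @return object of class `gamma_dfe`: `beta`, `Es`, `lambda0`, `logL`,
#'   `converged`, the demography, and the Nes grid used.
#' @export
fit_selected <- function(fsfs0, demog, init_s = -0.1, init_beta = 0.5,
                         tie_scale = TRUE, mu_ratio = 1,
                         nes_grid = default_nes_grid(),
                         n_restarts = 5, seed = 1) {
  stopifnot(inherits(fsfs0, "folded_sfs"), inherits(demog, "demography_fit"))
  obs <- fsfs0$bins
  n <- fsfs0$n
  L <- sum(obs)
  if (tie_scale && !is.finite(demog$lambda_site))
    stop("tie_scale = TRUE needs a demography fitted by fit_neutral()")
  PHI <- dfe_phi_matrix(demog, n, nes_grid)
  s_grid_abs <- nes_grid / demog$ne1
  lam_tied <- if (tie_scale) demog$lambda_site * L * mu_ratio else NA_real_
  nll <- function(p) {
    beta <- exp(p[1]); Es <- exp(p[2])
    if (!is.finite(beta) || !is.finite(Es) || beta > 50) return(1e12)
    w <- gamma_class_weights(beta, Es, s_grid_abs)
    phi <- as.vector(PHI %*% w)
    # free scale: Poisson profile MLE is S0 / sum(phi) (bins sum to L)
    lam <- if (tie_scale) lam_tied else sum(obs[-1]) / max(sum(phi), 1e-300)
    seg <- lam * phi
    e <- c(max(L - sum(seg), 1e-9), seg)
    v <- -sum(dpois(obs, pmax(e, 1e-12), log = TRUE))
    if (!is.finite(v)) 1e12 else v
  }
  st1 <- c(log(init_beta), log(abs(init_s)))
  jit <- with_seed(derive_seed(seed, 72),
                   replicate(n_restarts, rnorm(2, 0, 0.7), simplify = FALSE))
  starts <- c(list(st1), lapply(jit, function(j) st1 + j))
  best <- NULL
  for (st in starts) {
    f <- try(optim(st, nll, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-10)),
             silent = TRUE)
    if (inherits(f, "try-error")) next
    if (is.null(best) || f$value < best$value) best <- f
  }
  if (is.null(best)) stop("DFE fit failed from every start")
  beta <- exp(best$par[1]); Es <- exp(best$par[2])
  w_hat <- gamma_class_weights(beta, Es, s_grid_abs)
  phi_hat <- as.vector(PHI %*% w_hat)
  lam_hat <- if (tie_scale) lam_tied else
    sum(obs[-1]) / max(sum(phi_hat), 1e-300)
  structure(list(beta = beta, Es = Es,
                 lambda0 = lam_hat,
                 logL = -best$value, converged = best$convergence == 0,
                 demography = demog, nes_grid = nes_grid, n = n, L0 = L,
                 tie_scale = tie_scale),
            class = "gamma_dfe")
}

#' @export
print.gamma_dfe <- function(x, ...) {
  cat(sprintf("gamma DFE: beta = %.4g, E(s) = %.4g (logL = %.3f, %s)\n",
              x$beta, x$Es, x$logL,
              ifelse(isTRUE(x$converged), "converged", "not converged")))
  print(round(nes_class_proportions(x), 4))
  invisible(x)
}

#' Gamma mass over the standard scaled-selection classes
#'
#' Proportions of a gamma distribution with shape `beta` and mean `mean_nes`
#' over the classes `0-1`, `1-10`, `10-100` and `>100` of `Nes`.
#'
#' @param beta gamma shape (> 0).
#' @param mean_nes mean scaled strength (> 0).
#' @param breaks class boundaries (default `c(1, 10, 100)`).
#' @return named proportions summing to 1.
#' @export
#' @examples
#' gamma_class_proportions(1, 1)   # exponential: P(0-1) = 1 - exp(-1)
gamma_class_proportions <- function(beta, mean_nes, breaks = c(1, 10, 100)) {
  stopifnot(beta > 0, mean_nes > 0)
  nm <- c(paste0(c(0, breaks[-length(breaks)]), "-", breaks),
          paste0(">", breaks[length(breaks)]))
  if (!is.finite(mean_nes / beta))   # off-scale mean: everything is lethal
    return(setNames(c(rep(0, length(breaks)), 1), nm))
  edges <- c(0, breaks, Inf)
  p <- diff(pgamma(edges, shape = beta, scale = mean_nes / beta))
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  setNames(p, ifelse(is.finite(hi), paste0(lo, "-", hi), paste0(">", lo)))
}

#' Scaled-selection class proportions of a fitted DFE
#'
#' Converts the fitted `(beta, Es)` into proportions over the `Nes` classes
#' `{0-1, 1-10, 10-100, >100}`. The effective size used for scaling defaults
#' to the most recent epoch (`ne1 * nu`).
#'
#' @param dfe a [fit_selected()] result.
#' @param ne_scale effective size for the `Nes` product; default `ne1 * nu`
#'   of the attached demography.
#' @return named proportions summing to 1.
#' @export
nes_class_proportions <- function(dfe, ne_scale = NULL) {
  stopifnot(inherits(dfe, "gamma_dfe"))
  if (is.null(ne_scale))
    ne_scale <- dfe$demography$ne1 * dfe$demography$nu
  gamma_class_proportions(dfe$beta, ne_scale * dfe$Es)
}

#' Fit demography and DFE across SFS replicates
#'
#' Runs [fit_neutral()] then [fit_selected()] on each (0-fold, 4-fold)
#' replicate pair, e.g. the output of [build_replicates()] at one sample
#' size. Replicates whose fits error out or fail to converge are recorded
#' and excluded from the summary.
#'
#' @param sfs0_reps,sfs4_reps lists of [folded_sfs()] replicates (equal
#'   length).
#' @param ne1 rescaled ancestral size.
#' @param tie_scale,mu_ratio passed to [fit_selected()].
#' @param seed seed for the optimiser restarts.
#' @return list with `fits` (one row per replicate: `replicate, beta, Es,
#'   nu, t2, logL0, logL4, converged`), `beta` (converged beta values),
#'   `class_summary` (mean and SE of the four Nes class proportions over
#'   converged replicates) and `n_failed`.
#' @export
run_replicates <- function(sfs0_reps, sfs4_reps, ne1 = 100,
                           tie_scale = TRUE, mu_ratio = 1, seed = 1) {
  stopifnot(length(sfs0_reps) == length(sfs4_reps))
  reps <- length(sfs0_reps)
  rows <- vector("list", reps)
  props <- matrix(NA_real_, reps, 4)
  for (r in seq_len(reps)) {
    res <- try({
      dm <- fit_neutral(sfs4_reps[[r]], ne1 = ne1,
                        seed = derive_seed(seed, 500 + r))
      dfe <- fit_selected(sfs0_reps[[r]], dm, tie_scale = tie_scale,
                          mu_ratio = mu_ratio,
                          seed = derive_seed(seed, 900 + r))
      list(dm = dm, dfe = dfe)
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      rows[[r]] <- data.frame(replicate = r, beta = NA_real_, Es = NA_real_,
                              nu = NA_real_, t2 = NA_real_, logL0 = NA_real_,
                              logL4 = NA_real_, converged = FALSE)
      next
    }
    conv <- isTRUE(res$dm$converged) && isTRUE(res$dfe$converged)
    rows[[r]] <- data.frame(replicate = r, beta = res$dfe$beta,
                            Es = res$dfe$Es, nu = res$dm$nu, t2 = res$dm$t2,
                            logL0 = res$dfe$logL, logL4 = res$dm$logL,
                            converged = conv)
    if (conv) props[r, ] <- nes_class_proportions(res$dfe)
  }
  fits <- do.call(rbind, rows)
  ok <- fits$converged
  cs <- data.frame(class = names(gamma_class_proportions(1, 1)),
                   mean = colMeans(props[ok, , drop = FALSE]),
                   se = apply(props[ok, , drop = FALSE], 2, se_mean),
                   stringsAsFactors = FALSE, row.names = NULL)
  list(fits = fits, beta = fits$beta[ok], class_summary = cs,
       n_failed = sum(!ok))
}
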