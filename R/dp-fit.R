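#' Configuration for the Dirichlet-process beta-binomial sampler
#'
#' Defaults follow common practice for read-count clustering of deeply
#' sequenced somatic mutations: 10,000 MCMC iterations with a burn-in of
#' 1,000, Dirichlet-process concentration fixed at 1, a Beta(1, 1) base
#' measure on cellular prevalence, a Gamma(shape 1.0, rate 0.001) prior on
#' the beta-binomial precision, and a sequencing error floor of 0.001 on
#' the emission mean.
#'
#' @param iterations Total MCMC iterations.
#' @param burn_in Burn-in iterations (must be < `iterations`).
#' @param concentration Dirichlet-process concentration parameter.
#' @param base_alpha,base_beta Beta base-measure parameters for prevalence.
#' @param precision_shape,precision_rate Gamma prior on the beta-binomial
#'   precision.
#' @param error_rate Floor/ceiling applied to the emission mean VAF; also
#'   the minimum cluster prevalence (clusters below it are merged into
#'   their nearest neighbor at consensus time).
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @param aux_components Auxiliary components for the assignment update.
#' @param phi_proposal_sd,s_proposal_sd Random-walk proposal scales
#'   (logit-prevalence and log-precision).
#' @param largest_by `"prevalence"` (default: the dominant clone is the one
#'   with the highest posterior mean cellular prevalence) or `"members"`
#'   (most mutations).
#' @param seed Integer seed.
#' @return A list of class `dp_config`.
#' @export
dp_config <- function(iterations = 10000, burn_in = 1000,
                      concentration = 1, base_alpha = 1, base_beta = 1,
                      precision_shape = 1.0, precision_rate = 0.001,
                      error_rate = 0.001, thin = 1, aux_components = 3,
                      phi_proposal_sd = 0.5, s_proposal_sd = 0.3,
                      largest_by = c("prevalence", "members"),
                      seed = 1L) {
  largest_by <- match.arg(largest_by)
  if (burn_in >= iterations) stop_config("burn_in must be smaller than iterations")
  if (any(c(concentration, base_alpha, base_beta, precision_shape,
    precision_rate) <= 0)) {
    stop_config("rates and shapes must be positive")
  }
  if (error_rate <= 0 || error_rate >= 0.5) {
    stop_config("error_rate must lie in (0, 0.5)")
  }
  structure(list(
    iterations = as.integer(iterations), burn_in = as.integer(burn_in),
    concentration = concentration, base_alpha = base_alpha,
    base_beta = base_beta, precision_shape = precision_shape,
    precision_rate = precision_rate, error_rate = error_rate,
    thin = as.integer(thin), aux_components = as.integer(aux_components),
    phi_proposal_sd = phi_proposal_sd, s_proposal_sd = s_proposal_sd,
    largest_by = largest_by, seed = as.integer(seed)
  ), class = "dp_config")
}

# beta-binomial log density with mean/precision parameterization;
# vectorized over xi (and a, d when matching length)
bb_loglik <- function(a, d, xi, s) {
  al <- xi * s
  be <- (1 - xi) * s
  lbeta(a + al, d - a + be) - lbeta(al, be)
}

# emission mean for one mutation at prevalence phi (vectorized over phi)
emission_xi <- function(phi, branch, tcn, ascn, error_rate) {
  v <- vaf_expected(phi, branch, tcn, ascn)
  pmin(pmax(v, error_rate), 1 - error_rate)
}

#' Fit the Dirichlet-process beta-binomial mixture for one patient
#'
#' Clusters a patient's mutations over cellular prevalence with a
#' Dirichlet-process mixture: assignments follow a Chinese-restaurant
#' process (concentration from the config) with a Beta base measure on
#' prevalence; read counts follow a beta-binomial emission whose mean is
#' the copy-number-aware expected VAF of the cluster prevalence
#' ([vaf_expected()], clipped at the error rate) and whose precision has a
#' Gamma prior.  Sampling uses collapsed assignment updates with auxiliary
#' components and random-walk Metropolis updates for the prevalences
#' (logit scale) and the precision (log scale).
#'
#' Mutations are put in canonical `(chrom, pos, ref, alt)` order before
#' seeding, so results are invariant to input row order.  Identical seed
#' and input give an identical trace.
#'
#' @param mutations Adjusted mutation tibble for one patient (from
#'   [adjust_vaf()]): needs `alt_reads, depth, branch_used, tcn, ascn`, and
#'   `chrom, pos, ref, alt` for canonical ordering.  Calls flagged
#'   `excluded` must be removed by the caller ([infer_architecture()] does).
#' @param config A [dp_config()] object.
#' @return An object of class `dp_fit`: the post-burn-in trace of
#'   assignments (`z`, samples x mutations), per-mutation prevalences
#'   (`phi`), precision draws (`s`), and the canonically ordered input.
#' @export
fit_patient <- function(mutations, config = dp_config()) {
  if (!inherits(config, "dp_config")) stop_config("config must come from dp_config()")
  check_columns(mutations,
    c("alt_reads", "depth", "branch_used", "tcn", "ascn", "chrom", "pos"),
    what = "adjusted mutations")
  if (nrow(mutations) == 0) stop_validation("fit_patient needs at least one mutation")
  ord <- order(mutations$chrom, mutations$pos,
    if ("ref" %in% names(mutations)) mutations$ref else seq_len(nrow(mutations)),
    if ("alt" %in% names(mutations)) mutations$alt else seq_len(nrow(mutations)))
  mut <- mutations[ord, ]
  n <- nrow(mut)
  a <- mut$alt_reads
  d <- mut$depth
  branch <- mut$branch_used
  tcn <- mut$tcn
  ascn <- mut$ascn
  err <- config$error_rate

  set.seed(config$seed)
  # initial state: every mutation in its own cluster at its TCF estimate
  tcf0 <- estimate_tcf(a / d, mut$region_class %||% rep("neutral", n),
    tcn, ascn)$tcf
  phi <- pmin(pmax(tcf0, err), 1 - err)
  z <- seq_len(n)
  s <- config$precision_shape / config$precision_rate

  n_keep <- (config$iterations - config$burn_in) %/% config$thin
  z_trace <- matrix(NA_integer_, n_keep, n)
  phi_trace <- matrix(NA_real_, n_keep, n)
  s_trace <- numeric(n_keep)
  keep_i <- 0L

  ll_point <- function(i, phis) {
    xi <- emission_xi(phis, branch[i], tcn[i], ascn[i], err)
    bb_loglik(a[i], d[i], xi, s)
  }

  m_aux <- config$aux_components
  log_conc <- log(config$concentration / m_aux)

  for (iter in seq_len(config$iterations)) {
    # --- assignment updates (collapsed CRP with auxiliary components) ----
    for (i in seq_len(n)) {
      zi <- z[i]
      counts <- tabulate(z[-i], nbins = length(phi))
      occupied <- which(counts > 0)
      singleton <- counts[zi] == 0
      aux_phi <- rbeta(m_aux, config$base_alpha, config$base_beta)
      if (singleton) aux_phi[1] <- phi[zi]
      cand_phi <- c(phi[occupied], aux_phi)
      logw <- c(
        log(counts[occupied]) + ll_point(i, phi[occupied]),
        log_conc + ll_point(i, aux_phi)
      )
      logw <- logw - max(logw)
      pick <- sample.int(length(logw), 1, prob = exp(logw))
      if (pick <= length(occupied)) {
        z[i] <- occupied[pick]
      } else {
        # open a new cluster with the chosen auxiliary prevalence
        new_phi <- cand_phi[length(occupied) + (pick - length(occupied))]
        slot <- if (singleton) zi else length(phi) + 1L
        phi[slot] <- new_phi
        z[i] <- slot
      }
      # compact: drop empty slots so phi stays small
      if (length(phi) > n) {
        keep <- sort(unique(z))
        remap <- match(z, keep)
        phi <- phi[keep]
        z <- remap
      }
    }
    # relabel compactly every iteration
    keep <- sort(unique(z))
    phi <- phi[keep]
    z <- match(z, keep)

    # --- prevalence updates (random-walk Metropolis on the logit scale) --
    for (k in seq_along(phi)) {
      members <- which(z == k)
      cur <- phi[k]
      lcur <- stats::qlogis(cur)
      prop <- stats::plogis(lcur + rnorm(1, 0, config$phi_proposal_sd))
      xi_cur <- emission_xi(rep(cur, length(members)), branch[members],
        tcn[members], ascn[members], err)
      xi_prop <- emission_xi(rep(prop, length(members)), branch[members],
        tcn[members], ascn[members], err)
      ll_cur <- sum(bb_loglik(a[members], d[members], xi_cur, s))
      ll_prop <- sum(bb_loglik(a[members], d[members], xi_prop, s))
      # Beta base density + logit-transform Jacobian
      lp_cur <- (config$base_alpha - 1) * log(cur) +
        (config$base_beta - 1) * log(1 - cur) + log(cur * (1 - cur))
      lp_prop <- (config$base_alpha - 1) * log(prop) +
        (config$base_beta - 1) * log(1 - prop) + log(prop * (1 - prop))
      if (log(runif(1)) < ll_prop + lp_prop - ll_cur - lp_cur) {
        phi[k] <- prop
      }
    }

    # --- precision update (random-walk Metropolis on the log scale) ------
    xi_all <- emission_xi(phi[z], branch, tcn, ascn, err)
    s_prop <- exp(log(s) + rnorm(1, 0, config$s_proposal_sd))
    ll_s <- function(sv) {
      sum(bb_loglik(a, d, xi_all, sv)) +
        config$precision_shape * log(sv) - config$precision_rate * sv
    }
    if (log(runif(1)) < ll_s(s_prop) - ll_s(s)) s <- s_prop

    if (iter > config$burn_in &&
        (iter - config$burn_in) %% config$thin == 0) {
      keep_i <- keep_i + 1L
      z_trace[keep_i, ] <- z
      phi_trace[keep_i, ] <- phi[z]
      s_trace[keep_i] <- s
    }
  }

  structure(list(
    z = z_trace[seq_len(keep_i), , drop = FALSE],
    phi = phi_trace[seq_len(keep_i), , drop = FALSE],
    s = s_trace[seq_len(keep_i)],
    mutations = mut,
    config = config
  ), class = "dp_fit")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.dp_fit <- function(x, ...) {
  cat(sprintf(
    "<dp_fit> %d mutations, %d kept samples, posterior mean precision %.1f\n",
    ncol(x$z), nrow(x$z), mean(x$s)
  ))
  invisible(x)
}
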