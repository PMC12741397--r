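# Bayesian tip dating on a fixed topology: partitioned HKY(+I)+Gamma
# likelihood on a chronogram, uncorrelated lognormal (ULN) relaxed clock,
# constant-size serial coalescent tree prior, truncated-normal tip and
# node calibrations, Metropolis-Hastings MCMC, and HPD summaries.
# Time unit is Ma throughout; rates are substitutions/site/Ma.

#' Truncated-normal log density
#' @noRd
dtnorm_log <- function(x, mean, sd, lower = 0, upper = Inf) {
  if (x < lower || x > upper) return(-Inf)
  z <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  stats::dnorm(x, mean, sd, log = TRUE) - log(z)
}

# Lognormal parameters from a real-space mean and sd.
lnorm_params_real <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Prior set for tip dating
#'
#' Collects the calibration and hyperprior structure: truncated-normal
#' tip-age priors (tips not listed are fixed, default age 0),
#' truncated-normal tMRCA calibrations, a lognormal root prior
#' parameterised by its real-space mean and sd, the ULN clock hyperpriors
#' (normal prior on the mean log rate; exponential prior on the log-rate
#' sd), and a lognormal hyperprior on the coalescent population size.
#'
#' @param tip_ages named list; each element either
#'   `list(mean=, sd=, lower=0, upper=Inf)` (sampled, truncated normal)
#'   or `list(fixed=)` (known age).
#' @param node_calibrations list of `list(taxa=, mean=, sd=, lower=,
#'   upper=)` applied to the MRCA of `taxa`.
#' @param root `list(mean=, sd=)` real-space lognormal root-age prior, or
#'   `NULL` for no root calibration.
#' @param clock `list(mu_mean=, mu_sd=, sigma_rate=, estimate=, mu=,
#'   sigma=)`; when `estimate = FALSE` the hyperparameters `mu`/`sigma`
#'   of the branch-rate lognormal are fixed.
#' @param ne `list(meanlog=, sdlog=)` lognormal hyperprior on the
#'   coalescent population size (Ma units).
#' @return an object of class `prior_set`.
#' @export
prior_set <- function(tip_ages = list(), node_calibrations = list(),
                      root = NULL,
                      clock = list(), ne = list()) {
  clock <- utils::modifyList(
    list(mu_mean = log(0.02), mu_sd = 2, sigma_rate = 2,
         estimate = TRUE, mu = log(0.02), sigma = 0.3), clock)
  ne <- utils::modifyList(list(meanlog = log(0.5), sdlog = 2), ne)
  tip_ages <- lapply(tip_ages, function(p) {
    if (!is.null(p$fixed)) return(p)
    utils::modifyList(list(lower = 0, upper = Inf), p)
  })
  node_calibrations <- lapply(node_calibrations, function(p)
    utils::modifyList(list(lower = 0, upper = Inf), p))
  if (!is.null(root)) root <- c(root, lnorm_params_real(root$mean, root$sd))
  structure(list(tip_ages = tip_ages,
                 node_calibrations = node_calibrations,
                 root = root, clock = clock, ne = ne),
            class = "prior_set")
}

#' MCMC configuration for tip dating
#'
#' @param n_gen chain length in generations (one proposal each).
#' @param thin sampling interval (must divide `n_gen`).
#' @param burnin_frac fraction of the chain treated as burn-in (used for
#'   proposal-scale tuning during the run and as the default discard at
#'   summary time).
#' @param seed integer seed; identical seed and configuration give
#'   identical traces.
#' @param mode `"full"` (posterior), `"prior"` (likelihood off), or
#'   `"calibration"` (likelihood and coalescent off, so every sampled
#'   quantity's marginal is exactly its stated prior).
#' @param estimate_subst estimate per-partition HKY kappa, gamma shape
#'   and p_inv in-chain (diffuse priors); otherwise fixed at the supplied
#'   model values.
#' @param tune adapt proposal scales during burn-in.
#' @param scales named list of initial proposal scales.
#' @param move_weights named weights for the move classes (`ages`,
#'   `rates`, `hyper`, `subst`; optionally `age_rate`, `subtree` and
#'   `scale_all` for the likelihood-invariant joint operators, which
#'   otherwise default to fractions of `ages`).
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_gen = 2e6, thin = 200L, burnin_frac = 0.10,
                        seed = 1L,
                        mode = c("full", "prior", "calibration"),
                        estimate_subst = TRUE, tune = TRUE,
                        scales = list(), move_weights = list()) {
  mode <- match.arg(mode)
  stopifnot(burnin_frac >= 0, burnin_frac < 1, n_gen >= thin)
  if (n_gen %% thin != 0)
    stop("sampling interval (thin) must divide chain length (n_gen)")
  scales <- utils::modifyList(
    list(root = 0.5, tip = 0.05, rate = 0.4, sigma = 0.3, ne = 0.5,
         subst = 0.2), scales)
  move_weights <- utils::modifyList(
    list(ages = 0.40, rates = 0.30, hyper = 0.15, subst = 0.15),
    move_weights)
  structure(list(n_gen = as.integer(n_gen), thin = as.integer(thin),
                 burnin_frac = burnin_frac, seed = as.integer(seed),
                 mode = mode, estimate_subst = estimate_subst,
                 tune = tune, scales = scales,
                 move_weights = move_weights),
            class = "mcmc_config")
}

#' Constant-size serial coalescent log density
#'
#' Standard serial coalescent with constant population size `Ne`:
#' lineage counts increase at sampling (tip) times and decrease at
#' coalescences; each interval with `k` lineages contributes
#' `exp(-choose(k,2) dt / Ne)` and each coalescence a factor `1/Ne`.
#'
#' @param chrono a [dated_tree], or a list with `tip_ages` and
#'   `node_ages` numeric vectors.
#' @param Ne population size parameter (time units of the ages).
#' @return the log density; `-Inf` for age configurations in which a
#'   coalescence occurs with fewer than two active lineages.
#' @export
coalescent_logprior <- function(chrono, Ne) {
  stopifnot(Ne > 0)
  if (inherits(chrono, "dated_tree")) {
    ntip <- length(chrono$topo$tip.label)
    tip_ages <- chrono$ages[seq_len(ntip)]
    node_ages <- chrono$ages[(ntip + 1L):length(chrono$ages)]
  } else {
    tip_ages <- chrono$tip_ages
    node_ages <- chrono$node_ages
  }
  serial_coalescent_ll(tip_ages, node_ages, Ne)
}

serial_coalescent_ll <- function(tip_ages, node_ages, Ne) {
  t <- c(tip_ages, node_ages)
  d <- c(rep(1L, length(tip_ages)), rep(-1L, length(node_ages)))
  o <- order(t, -d)                # at ties, sampling before coalescence
  t <- t[o]; d <- d[o]
  k <- cumsum(d)                   # lineages after each event
  if (any(d < 0L & (k - d) < 2L)) return(-Inf)
  kin <- k[-length(k)]             # lineages during each interval
  dt <- diff(t)
  -length(node_ages) * log(Ne) - sum(kin * (kin - 1) / 2 * dt) / Ne
}

#' Uncorrelated lognormal relaxed-clock log prior
#'
#' Sum of independent lognormal log densities over branch rates.
#'
#' @param rates positive per-branch substitution rates.
#' @param meanlog,sdlog lognormal parameters of the branch-rate
#'   distribution.
#' @return the summed log density.
#' @export
uln_clock_logprior <- function(rates, meanlog, sdlog) {
  stopifnot(all(rates > 0), sdlog > 0)
  sum(stats::dlnorm(rates, meanlog, sdlog, log = TRUE))
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval on the sorted samples containing
#' `ceiling(prob * n)` samples.
#'
#' @param x numeric samples.
#' @param prob interval mass (default 0.95).
#' @return `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  xs <- sort(x)
  n <- length(xs)
  nin <- min(n, max(1L, ceiling(prob * n)))
  if (nin == n) return(c(xs[1], xs[n]))
  w <- xs[nin:n] - xs[1:(n - nin + 1L)]
  i <- which.min(w)
  c(xs[i], xs[i + nin - 1L])
}

#' Effective sample size via autocorrelation time
#'
#' Geyer initial-positive-sequence estimator of the integrated
#' autocorrelation time.
#'
#' @param x numeric trace.
#' @return estimated ESS (clamped to `[1, length(x)]`).
#' @export
ess_estimate <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0 || !is.finite(stats::var(x))) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2L, 1000L), plot = FALSE,
                    demean = TRUE)$acf[-1]
  tau <- 1
  m <- 1
  while (m < length(rho)) {
    g <- rho[m] + (if (m + 1 <= length(rho)) rho[m + 1] else 0)
    if (!is.finite(g) || g <= 0) break
    tau <- tau + 2 * g
    m <- m + 2
  }
  max(1, min(n, n / tau))
}

#' Summarise MCMC traces
#'
#' Removes burn-in, then reports the median, shortest-interval 95% HPD
#' and ESS of every sampled quantity. Invariant to sample order (up to
#' the ESS, which is order-dependent by definition).
#'
#' @param traces data frame of retained samples (from [mcmc_run]).
#' @param burn_in_frac fraction of rows discarded from the front.
#' @return a data frame of class `posterior_summary` with one row per
#'   parameter: `param`, `median`, `hpd_lower`, `hpd_upper`, `ess`, `n`.
#' @export
summarize_posterior <- function(traces, burn_in_frac = 0.10) {
  stopifnot(is.data.frame(traces), burn_in_frac >= 0, burn_in_frac < 1)
  drop <- floor(nrow(traces) * burn_in_frac)
  if (nrow(traces) - drop < 1L) stop("no samples remain after burn-in")
  kept <- traces[seq.int(drop + 1L, nrow(traces)), , drop = FALSE]
  cols <- names(kept)[vapply(kept, is.numeric, TRUE)]
  cols <- setdiff(cols, "gen")
  rows <- lapply(cols, function(cn) {
    x <- kept[[cn]]
    h <- hpd_interval(x)
    data.frame(param = cn, median = stats::median(x), hpd_lower = h[1],
               hpd_upper = h[2], ess = ess_estimate(x), n = length(x),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("posterior_summary", "data.frame"))
}

#' Trace column of an internal node's age
#'
#' @param topology the `phylo` used for the run.
#' @param taxa tip labels whose MRCA age is wanted.
#' @return the trace column name (`"age_n<k>"`).
#' @export
mrca_age_column <- function(topology, taxa) {
  if (length(taxa) == 1L) {
    stopifnot(taxa %in% topology$tip.label)
    return(paste0("tip_", taxa))
  }
  paste0("age_n", ape::getMRCA(topology, taxa))
}

# ---------------------------------------------------------------------------
# MCMC internals

mcmc_state_init <- function(topo, priors, jitter = 0) {
  ntip <- length(topo$tip.label)
  nnode <- topo$Nnode
  age <- numeric(ntip + nnode)
  sampled_tips <- integer()
  for (i in seq_len(ntip)) {
    nm <- topo$tip.label[i]
    p <- priors$tip_ages[[nm]]
    if (is.null(p)) {
      age[i] <- 0
    } else if (!is.null(p$fixed)) {
      age[i] <- p$fixed
    } else {
      age[i] <- min(max(p$mean, p$lower), if (is.finite(p$upper)) p$upper
                    else p$mean)
      sampled_tips <- c(sampled_tips, i)
    }
  }
  cal_node <- integer(0)
  cal <- priors$node_calibrations
  if (length(cal))
    cal_node <- vapply(cal, function(p) ape::getMRCA(topo, p$taxa), 1L)
  root <- ntip + 1L
  po <- ape::reorder.phylo(topo, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    lower <- age[ch] + 0.02 * (1 + age[ch]) * (1 + jitter * stats::runif(1))
    if (age[pa] < lower) age[pa] <- lower
  }
  for (j in seq_along(cal_node)) {
    n <- cal_node[j]
    kids <- po$edge[po$edge[, 1] == n, 2]
    lo <- max(age[kids])
    target <- max(cal[[j]]$mean, cal[[j]]$lower)
    if (target > lo) age[n] <- target
  }
  # re-propagate monotonicity upwards after calibration nudges
  for (e in seq_len(nrow(po$edge))) {
    pa <- po$edge[e, 1]; ch <- po$edge[e, 2]
    if (age[pa] <= age[ch]) age[pa] <- age[ch] + 0.02 * (1 + age[ch])
  }
  if (!is.null(priors$root)) {
    kids <- po$edge[po$edge[, 1] == root, 2]
    age[root] <- max(age[root], max(age[kids]) * 1.05, priors$root$mean)
  }
  list(age = age, sampled_tips = sampled_tips, cal_node = cal_node,
       root = root, po = po, tip_label = topo$tip.label)
}

# Precomputed prior context: everything posterior_parts needs as flat
# vectors, derived once per run.
prior_context <- function(st, priors, use_coal) {
  tipi <- st$sampled_tips
  tp <- lapply(st$tip_label[tipi], function(nm) priors$tip_ages[[nm]])
  tz <- function(p) log(stats::pnorm(p$upper, p$mean, p$sd) -
                          stats::pnorm(p$lower, p$mean, p$sd))
  cal <- priors$node_calibrations
  list(pa = st$po$edge[, 1], ch = st$po$edge[, 2],
       ntip = length(st$tip_label), root = st$root,
       tipi = tipi,
       tipm = vapply(tp, `[[`, 0, "mean"), tips = vapply(tp, `[[`, 0, "sd"),
       tiplo = vapply(tp, `[[`, 0, "lower"),
       tiphi = vapply(tp, `[[`, 0, "upper"),
       tiplz = vapply(tp, tz, 0),
       caln = st$cal_node,
       calm = vapply(cal, `[[`, 0, "mean"), cals = vapply(cal, `[[`, 0, "sd"),
       callo = vapply(cal, `[[`, 0, "lower"),
       calhi = vapply(cal, `[[`, 0, "upper"),
       callz = vapply(cal, tz, 0),
       root_prior = priors$root, clock = priors$clock, ne = priors$ne,
       use_coal = use_coal)
}

# Diffuse priors on the in-chain substitution parameters.
subst_logprior <- function(part_models) {
  if (is.null(part_models)) return(0)
  s <- 0
  for (m in part_models) {
    s <- s + stats::dnorm(log(m$rates[2] / m$rates[1]), log(2), 1.5,
                          log = TRUE)
    if (is.finite(m$alpha))
      s <- s + stats::dnorm(log(m$alpha), 0, 1.5, log = TRUE)
    # p_inv uniform(0,1): constant
  }
  s
}

# All log-density pieces for the current state. `llik_cache` skips the
# likelihood when the move touched neither ages, rates, nor models.
posterior_parts <- function(state, pc, prep, use_lik, llik_cache = NULL,
                            lcoal_cache = NULL) {
  age <- state$age
  dur <- age[pc$pa] - age[pc$ch]
  if (any(dur <= 0)) return(list(total = -Inf))

  lcal <- 0
  if (length(pc$tipi)) {
    x <- age[pc$tipi]
    if (any(x < pc$tiplo | x > pc$tiphi)) return(list(total = -Inf))
    lcal <- sum(stats::dnorm(x, pc$tipm, pc$tips, log = TRUE)) -
      sum(pc$tiplz)
  }
  if (length(pc$caln)) {
    x <- age[pc$caln]
    if (any(x < pc$callo | x > pc$calhi)) return(list(total = -Inf))
    lcal <- lcal + sum(stats::dnorm(x, pc$calm, pc$cals, log = TRUE)) -
      sum(pc$callz)
  }
  if (!is.null(pc$root_prior))
    lcal <- lcal + stats::dlnorm(age[pc$root], pc$root_prior$meanlog,
                                 pc$root_prior$sdlog, log = TRUE)
  if (!is.finite(lcal)) return(list(total = -Inf))

  lcoal <- 0
  if (pc$use_coal) {
    if (!is.null(lcoal_cache)) {
      lcoal <- lcoal_cache        # move touched neither ages nor Ne
    } else {
      lcoal <- serial_coalescent_ll(age[seq_len(pc$ntip)],
                                    age[(pc$ntip + 1L):length(age)],
                                    exp(state$logNe))
      if (!is.finite(lcoal)) return(list(total = -Inf))
    }
  }
  clock <- pc$clock
  lclock <- sum(stats::dnorm(state$lograte, state$mu, state$sigma,
                             log = TRUE))
  lhyper <- stats::dnorm(state$logNe, pc$ne$meanlog, pc$ne$sdlog,
                         log = TRUE)
  if (clock$estimate) {
    if (state$sigma <= 0) return(list(total = -Inf))
    lhyper <- lhyper +
      stats::dnorm(state$mu, clock$mu_mean, clock$mu_sd, log = TRUE) +
      stats::dexp(state$sigma, clock$sigma_rate, log = TRUE)
  }
  llik <- 0
  if (use_lik) {
    if (!is.null(llik_cache)) {
      llik <- llik_cache
    } else {
      blens <- dur * exp(state$lograte)
      llik <- eval_chain_lik(prep, blens)
      if (!is.finite(llik)) return(list(total = -Inf))
    }
  }
  list(total = llik + lcoal + lclock + lcal + lhyper + state$lsub,
       llik = llik, lcoal = lcoal)
}

eval_chain_lik <- function(prep, blens) {
  peel_total_cpp(prep$edge, prep$ntip, prep$parts, blens)
}

#' Tip-dating MCMC
#'
#' Metropolis-Hastings sampler over node ages (bounded by neighbours),
#' dated-tip ages, per-branch log rates, a joint age-and-rate move that
#' slides a node age while rescaling the adjacent branch rates to keep
#' branch lengths fixed (this traverses the rate-time ridge without
#' likelihood evaluations), the clock hyperparameters (Gibbs update of
#' the mean log rate; multiplicative walk on the rate sd), the
#' coalescent population size, and optionally the per-partition HKY
#' kappa, gamma shape and p_inv. Branch lengths for the likelihood are
#' branch durations times branch rates. The posterior is proportional to
#' likelihood x serial coalescent x ULN clock x calibration priors x
#' hyperpriors.
#'
#' @param x alignment (`supermatrix`, character matrix, or named
#'   character vector); may be `NULL` in `"prior"`/`"calibration"` modes.
#' @param topology rooted `phylo` over the taxa (fixed).
#' @param priors a [prior_set].
#' @param config an [mcmc_config].
#' @param models a single [subst_model] or named per-partition list (the
#'   dating model, typically HKY+I+Gamma per partition).
#' @param partitions named list of site-index vectors (or `NULL`; a
#'   `supermatrix` supplies its own).
#' @return a list of class `mcmc_run` with `traces` (data frame, one row
#'   per retained sample), `topology`, `config`, `priors`, and
#'   `acceptance` (per-move acceptance rates).
#' @export
mcmc_run <- function(x, topology, priors, config, models = NULL,
                     partitions = NULL) {
  stopifnot(inherits(priors, "prior_set"), inherits(config, "mcmc_config"))
  # calibrations on clades absent from this topology (e.g. a collapsed
  # focal pair) do not apply
  priors$node_calibrations <- Filter(function(p)
    all(p$taxa %in% topology$tip.label), priors$node_calibrations)
  use_lik <- config$mode == "full"
  use_coal <- config$mode != "calibration"
  if (use_lik && is.null(x))
    stop("an alignment is required in mode='full'")

  prep <- NULL
  part_models <- NULL
  if (use_lik) {
    if (is.null(models)) stop("models required in mode='full'")
    if (inherits(x, "supermatrix") && is.null(partitions))
      partitions <- x$partitions
    if (inherits(models, "subst_model")) {
      nsite <- if (inherits(x, "supermatrix")) ncol(x$matrix) else
        ncol(alignment_codes(x))
      if (is.null(partitions)) partitions <- list(all = seq_len(nsite))
      models <- stats::setNames(rep(list(models), length(partitions)),
                                names(partitions))
    }
    prep <- prep_likelihood(x, topology, models, partitions)
    part_models <- models[names(partitions)]
  }

  with_seed(config$seed, {
    for (try in 0:20) {
      st <- mcmc_state_init(topology, priors, jitter = try)
      pc <- prior_context(st, priors, use_coal)
      state <- list(age = st$age,
                    lograte = rep(priors$clock$mu, nrow(st$po$edge)),
                    mu = priors$clock$mu, sigma = priors$clock$sigma,
                    logNe = priors$ne$meanlog,
                    part_models = part_models,
                    lsub = subst_logprior(part_models))
      lp <- posterior_parts(state, pc, prep, use_lik)
      if (is.finite(lp$total)) break
      if (try == 20) stop("could not find a valid starting state")
    }
    if (try > 0)
      message("re-initialised starting state ", try, " time(s)")
    run_chain(state, st, pc, priors, config, prep, use_lik, topology)
  })
}

run_chain <- function(state, st, pc, priors, config, prep, use_lik,
                      topology) {
  ntip <- length(topology$tip.label)
  edge <- st$po$edge
  nedge <- nrow(edge)
  internal <- (ntip + 1L):(ntip + topology$Nnode)
  children <- lapply(seq_len(ntip + topology$Nnode), function(n)
    edge[edge[, 1] == n, 2])
  # adjacent edges of each node (for the joint age-rate move)
  adj_edges <- lapply(seq_len(ntip + topology$Nnode), function(n)
    which(edge[, 1] == n | edge[, 2] == n))
  # clade membership (for the subtree-translate move): nodes of each
  # internal non-root clade, and whether all its tips have sampled ages
  clade_nodes <- vector("list", ntip + topology$Nnode)
  for (n in internal) {
    members <- n
    repeat {
      kids <- edge[edge[, 1] %in% members, 2]
      new <- setdiff(kids, members)
      if (!length(new)) break
      members <- c(members, new)
    }
    clade_nodes[[n]] <- members
  }
  clade_movable <- vapply(seq_len(ntip + topology$Nnode), function(n) {
    if (is.null(clade_nodes[[n]]) || n == st$root) return(FALSE)
    tips_in <- clade_nodes[[n]][clade_nodes[[n]] <= ntip]
    all(tips_in %in% st$sampled_tips)
  }, TRUE)
  translatable <- internal[clade_movable[internal]]
  scaled_nodes <- c(internal, st$sampled_tips)   # rate-time rescale set
  parent <- integer(ntip + topology$Nnode)
  parent[edge[, 2]] <- edge[, 1]
  clock <- priors$clock
  scales <- config$scales
  estimate_subst <- config$estimate_subst && !is.null(state$part_models)
  movable <- c(internal, st$sampled_tips)

  lp <- posterior_parts(state, pc, prep, use_lik)
  stopifnot(is.finite(lp$total))

  w <- config$move_weights
  mv <- c(ages = w$ages, age_rate = w$age_rate %||% (w$ages * 0.75),
          subtree = if (length(translatable))
            w$subtree %||% (w$ages * 0.5) else 0,
          scale_all = w$scale_all %||% (w$ages * 0.4),
          rates = w$rates, hyper = w$hyper,
          subst = if (estimate_subst) w$subst else 0)
  if (!use_lik)   # redundant without a likelihood
    mv[c("age_rate", "subtree", "scale_all")] <- 0
  mv <- mv / sum(mv)
  mv_names <- names(mv)

  nsamp <- config$n_gen %/% config$thin
  label_cols <- c(paste0("age_n", internal),
                  paste0("tip_", st$tip_label[st$sampled_tips]))
  sub_cols <- if (estimate_subst)
    unlist(lapply(names(state$part_models), function(pn)
      paste0(c("kappa_", "alpha_", "pinv_"), pn))) else character()
  trace <- matrix(NA_real_, nsamp,
                  4L + length(label_cols) + 3L + length(sub_cols))
  colnames(trace) <- c("gen", "lnpost", "lnlik", "mean_rate", label_cols,
                       "mu", "sigma", "ne", sub_cols)

  acc <- prop <- stats::setNames(numeric(length(mv)), mv_names)
  accw <- propw <- c(root = 0, tip = 0, rate = 0, sigma = 0, ne = 0,
                     subst = 0)
  tune_until <- floor(config$n_gen * config$burnin_frac)
  row <- 0L
  kinds <- sample(mv_names, config$n_gen, replace = TRUE, prob = mv)

  for (gen in seq_len(config$n_gen)) {
    kind <- kinds[gen]
    accepted <- FALSE
    if (kind == "ages") {
      pick <- movable[sample.int(length(movable), 1L)]
      old <- state$age[pick]
      if (pick > ntip && pick != st$root) {
        lo <- max(state$age[children[[pick]]])
        hi <- state$age[parent[pick]]
        state$age[pick] <- stats::runif(1, lo, hi)   # symmetric
      } else if (pick == st$root) {
        state$age[pick] <- old + stats::rnorm(1, 0, scales$root)
        propw["root"] <- propw["root"] + 1
      } else {
        state$age[pick] <- old + stats::rnorm(1, 0, scales$tip)
        propw["tip"] <- propw["tip"] + 1
      }
      lp2 <- posterior_parts(state, pc, prep, use_lik)
      if (log(stats::runif(1)) < lp2$total - lp$total) {
        lp <- lp2; accepted <- TRUE
        if (pick == st$root) accw["root"] <- accw["root"] + 1
        if (pick <= ntip) accw["tip"] <- accw["tip"] + 1
      } else state$age[pick] <- old
    } else if (kind == "age_rate") {
      # slide a node age, rescaling adjacent branch rates so that every
      # adjacent branch length stays fixed: likelihood is unchanged and
      # the log-rate transform is a translation (unit Jacobian)
      pick <- movable[sample.int(length(movable), 1L)]
      old <- state$age[pick]
      old_lr <- state$lograte
      if (pick > ntip && pick != st$root) {
        lo <- max(state$age[children[[pick]]])
        hi <- state$age[parent[pick]]
        newage <- stats::runif(1, lo, hi)
      } else if (pick == st$root) {
        newage <- old + stats::rnorm(1, 0, scales$root)
        if (newage <= max(state$age[children[[pick]]])) newage <- NA
      } else {
        newage <- old + stats::rnorm(1, 0, scales$tip)
        if (newage >= state$age[parent[pick]] || newage < 0) newage <- NA
      }
      if (!is.na(newage)) {
        es <- adj_edges[[pick]]
        dur_old <- state$age[edge[es, 1]] - state$age[edge[es, 2]]
        state$age[pick] <- newage
        dur_new <- state$age[edge[es, 1]] - state$age[edge[es, 2]]
        if (all(dur_new > 0)) {
          state$lograte[es] <- old_lr[es] + log(dur_old) - log(dur_new)
          lp2 <- posterior_parts(state, pc, prep, use_lik,
                                 llik_cache = lp$llik)
          if (log(stats::runif(1)) < lp2$total - lp$total) {
            lp <- lp2; accepted <- TRUE
          } else {
            state$age[pick] <- old; state$lograte <- old_lr
          }
        } else state$age[pick] <- old
      }
    } else if (kind == "subtree") {
      # translate every age in a clade by the same offset, rescaling the
      # rate of the clade's stem edge so its branch length (and hence
      # the likelihood) is unchanged; unit Jacobian in log-rate space
      n <- translatable[sample.int(length(translatable), 1L)]
      delta <- stats::rnorm(1, 0, scales$tip)
      members <- clade_nodes[[n]]
      old_age <- state$age
      old_lr <- state$lograte
      state$age[members] <- state$age[members] + delta
      stem <- which(edge[, 2] == n)
      dur_old <- old_age[edge[stem, 1]] - old_age[n]
      dur_new <- state$age[edge[stem, 1]] - state$age[n]
      if (dur_new > 0 && all(state$age[members] >= 0)) {
        state$lograte[stem] <- old_lr[stem] + log(dur_old) - log(dur_new)
        lp2 <- posterior_parts(state, pc, prep, use_lik,
                               llik_cache = lp$llik)
        if (log(stats::runif(1)) < lp2$total - lp$total) {
          lp <- lp2; accepted <- TRUE
        } else {
          state$age <- old_age; state$lograte <- old_lr
        }
      } else {
        state$age <- old_age
      }
    } else if (kind == "scale_all") {
      # rate-time rescale: multiply every free age by c and shift every
      # branch's log rate to keep all branch lengths (and hence the
      # likelihood) fixed; Jacobian c^(number of scaled ages)
      logc <- stats::rnorm(1, 0, scales$scale_all %||% 0.2)
      cc <- exp(logc)
      old_age <- state$age
      old_lr <- state$lograte
      state$age[scaled_nodes] <- state$age[scaled_nodes] * cc
      dur_old <- old_age[edge[, 1]] - old_age[edge[, 2]]
      dur_new <- state$age[edge[, 1]] - state$age[edge[, 2]]
      if (all(dur_new > 0)) {
        state$lograte <- old_lr + log(dur_old) - log(dur_new)
        lp2 <- posterior_parts(state, pc, prep, use_lik,
                               llik_cache = lp$llik)
        lq <- length(scaled_nodes) * logc
        if (log(stats::runif(1)) < lp2$total - lp$total + lq) {
          lp <- lp2; accepted <- TRUE
        } else {
          state$age <- old_age; state$lograte <- old_lr
        }
      } else {
        state$age <- old_age
      }
    } else if (kind == "rates") {
      e <- sample.int(nedge, 1L)
      old <- state$lograte[e]
      state$lograte[e] <- old + stats::rnorm(1, 0, scales$rate)
      propw["rate"] <- propw["rate"] + 1
      lp2 <- posterior_parts(state, pc, prep, use_lik,
                             lcoal_cache = lp$lcoal)
      if (log(stats::runif(1)) < lp2$total - lp$total) {
        lp <- lp2; accepted <- TRUE; accw["rate"] <- accw["rate"] + 1
      } else state$lograte[e] <- old
    } else if (kind == "hyper") {
      which_h <- sample(c("mu", "sigma", "ne"), 1L)
      if (which_h == "mu" && clock$estimate) {
        v <- 1 / (nedge / state$sigma^2 + 1 / clock$mu_sd^2)
        m <- v * (sum(state$lograte) / state$sigma^2 +
                    clock$mu_mean / clock$mu_sd^2)
        state$mu <- stats::rnorm(1, m, sqrt(v))
        lp <- posterior_parts(state, pc, prep, use_lik,
                              llik_cache = lp$llik,
                              lcoal_cache = lp$lcoal)
        accepted <- TRUE
      } else if (which_h == "sigma" && clock$estimate) {
        old <- state$sigma
        state$sigma <- old * exp(stats::rnorm(1, 0, scales$sigma))
        propw["sigma"] <- propw["sigma"] + 1
        lp2 <- posterior_parts(state, pc, prep, use_lik,
                               llik_cache = lp$llik,
                               lcoal_cache = lp$lcoal)
        lq <- log(state$sigma / old)   # Jacobian of the log walk
        if (log(stats::runif(1)) < lp2$total - lp$total + lq) {
          lp <- lp2; accepted <- TRUE; accw["sigma"] <- accw["sigma"] + 1
        } else state$sigma <- old
      } else if (which_h == "ne") {
        old <- state$logNe
        state$logNe <- old + stats::rnorm(1, 0, scales$ne)
        propw["ne"] <- propw["ne"] + 1
        lp2 <- posterior_parts(state, pc, prep, use_lik,
                               llik_cache = lp$llik)
        if (log(stats::runif(1)) < lp2$total - lp$total) {
          lp <- lp2; accepted <- TRUE; accw["ne"] <- accw["ne"] + 1
        } else state$logNe <- old
      }
    } else if (kind == "subst") {
      pn <- sample(names(state$part_models), 1L)
      m <- state$part_models[[pn]]
      avail <- c("kappa",
                 if (is.finite(m$alpha)) "alpha",
                 if (m$pinv > 0) "pinv")
      parm <- avail[sample.int(length(avail), 1L)]
      old_m <- m
      old_lsub <- state$lsub
      kappa <- m$rates[2] / m$rates[1]
      lq <- 0
      if (parm == "kappa") {
        kappa2 <- kappa * exp(stats::rnorm(1, 0, scales$subst))
        lq <- log(kappa2 / kappa)
        m2 <- try(hky_model(kappa2, m$freq, m$pinv, m$alpha, m$ncat),
                  silent = TRUE)
      } else if (parm == "alpha" && is.finite(m$alpha)) {
        a2 <- m$alpha * exp(stats::rnorm(1, 0, scales$subst))
        lq <- log(a2 / m$alpha)
        m2 <- try(hky_model(kappa, m$freq, m$pinv, a2, m$ncat),
                  silent = TRUE)
      } else {
        lg <- stats::qlogis(min(max(m$pinv, 1e-8), 1 - 1e-8)) +
          stats::rnorm(1, 0, 4 * scales$subst)
        p2 <- stats::plogis(lg)
        lq <- log(p2 * (1 - p2)) -
          log(max(m$pinv * (1 - m$pinv), 1e-12))
        m2 <- try(hky_model(kappa, m$freq, p2, m$alpha, m$ncat),
                  silent = TRUE)
      }
      propw["subst"] <- propw["subst"] + 1
      if (!inherits(m2, "try-error")) {
        state$part_models[[pn]] <- m2
        state$lsub <- subst_logprior(state$part_models)
        pi_ <- which(names(state$part_models) == pn)
        if (use_lik)
          prep$parts[[pi_]] <- update_part_model(prep$parts[[pi_]], m2)
        lp2 <- posterior_parts(state, pc, prep, use_lik,
                               lcoal_cache = lp$lcoal)
        if (log(stats::runif(1)) < lp2$total - lp$total + lq) {
          lp <- lp2; accepted <- TRUE; accw["subst"] <- accw["subst"] + 1
        } else {
          state$part_models[[pn]] <- old_m
          state$lsub <- old_lsub
          if (use_lik)
            prep$parts[[pi_]] <- update_part_model(prep$parts[[pi_]],
                                                   old_m)
        }
      }
    }
    prop[kind] <- prop[kind] + 1
    if (accepted) acc[kind] <- acc[kind] + 1

    if (config$tune && gen <= tune_until && gen %% 250L == 0L) {
      for (s in names(scales)) {
        if (!s %in% names(propw)) next
        if (propw[s] >= 10) {
          r <- accw[s] / propw[s]
          scales[[s]] <- max(1e-4, scales[[s]] * exp(r - 0.3))
          accw[s] <- propw[s] <- 0
        }
      }
    }

    if (gen %% config$thin == 0L) {
      row <- row + 1L
      vals <- c(gen, lp$total, lp$llik %||% 0,
                mean(exp(state$lograte)),
                state$age[internal],
                state$age[st$sampled_tips],
                state$mu, state$sigma, exp(state$logNe))
      if (estimate_subst)
        vals <- c(vals, unlist(lapply(state$part_models, function(m)
          c(m$rates[2] / m$rates[1],
            if (is.finite(m$alpha)) m$alpha else Inf, m$pinv))))
      trace[row, ] <- vals
    }
  }
  structure(list(traces = as.data.frame(trace), topology = topology,
                 config = config, priors = priors,
                 acceptance = ifelse(prop > 0, acc / prop, NA)),
            class = "mcmc_run")
}

#' @export
print.mcmc_run <- function(x, ...) {
  cat(sprintf("mcmc_run: %d generations, %d retained samples, mode '%s'\n",
              x$config$n_gen, nrow(x$traces), x$config$mode))
  cat("acceptance:", paste(sprintf("%s=%.2f", names(x$acceptance),
                                   x$acceptance), collapse = ", "), "\n")
  invisible(x)
}
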