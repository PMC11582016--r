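#' Sampler configuration
#'
#' Settings for the built-in No-U-Turn Hamiltonian Monte Carlo sampler used
#' by all model-fitting functions. Defaults follow common practice for these
#' models: four chains of 2000 iterations each, the first 1000 as warmup
#' (step-size and diagonal-metric adaptation), no thinning.
#'
#' @param n_chains Number of chains (>= 1).
#' @param n_iter Total iterations per chain, including warmup.
#' @param n_warmup Warmup (adaptation) iterations per chain; must be smaller
#'   than `n_iter`.
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Integer seed; drawn at random if `NULL`.
#' @param target_accept Target acceptance statistic for step-size adaptation,
#'   in (0, 1).
#' @param max_treedepth Maximum doublings per NUTS trajectory.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4L, n_iter = 2000L, n_warmup = 1000L,
                           thin = 1L, seed = NULL,
                           target_accept = 0.8, max_treedepth = 10L) {
  stopifnot(
    n_chains >= 1, n_warmup < n_iter, thin >= 1,
    target_accept > 0, target_accept < 1, max_treedepth >= 1
  )
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  structure(
    list(
      n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
      n_warmup = as.integer(n_warmup), thin = as.integer(thin),
      seed = as.integer(seed), target_accept = target_accept,
      max_treedepth = as.integer(max_treedepth)
    ),
    class = "sampler_config"
  )
}

#' Sample a posterior with the built-in No-U-Turn sampler
#'
#' Generic entry point to the gradient-based sampler: supply a log density on
#' an unconstrained parameter space together with its gradient, and receive
#' posterior draws. All constrained parameters must be mapped to the
#' unconstrained scale by the caller (log for positive parameters, logit for
#' probabilities, multinomial-logit for simplexes), with the Jacobian
#' included in the density; `transform` maps draws back to the constrained
#' scale for storage.
#'
#' @param logdensity Function of an unconstrained numeric vector returning a
#'   list with elements `value` (scalar log density) and `grad` (gradient
#'   vector).
#' @param n_pars Dimension of the unconstrained space.
#' @param config A [sampler_config()].
#' @param init Optional numeric vector (or list of per-chain vectors) of
#'   initial unconstrained values; by default chains start from independent
#'   uniform(-2, 2) draws, retrying up to 100 times if the density is not
#'   finite there.
#' @param transform Function mapping a matrix of unconstrained draws (one row
#'   per draw) to constrained draws; defaults to the identity.
#' @param par_names Optional parameter names for the transformed draws.
#' @return An object of class `hz_draws`: posterior draws of shape
#'   iterations x chains x parameters plus divergence counts and sampler
#'   information.
#' @export
sample_posterior <- function(logdensity, n_pars, config = sampler_config(),
                             init = NULL, transform = identity,
                             par_names = NULL) {
  spec <- list(type = "rfun", logp = function(q) {
    res <- logdensity(q)
    if (!is.list(res)) res <- list(value = res[1], grad = attr(res, "grad"))
    res
  }, n_pars = as.integer(n_pars))
  fit_nuts(spec, n_pars, config, transform = transform, par_names = par_names,
    init = init)
}

# internal driver shared by all model fits
fit_nuts <- function(model_spec, n_pars, config, transform = identity,
                     par_names = NULL, init = NULL) {
  n_keep <- (config$n_iter - config$n_warmup) %/% config$thin
  chains <- vector("list", config$n_chains)
  divergences <- integer(config$n_chains)
  step_sizes <- accept <- depth <- numeric(config$n_chains)
  for (k in seq_len(config$n_chains)) {
    chain_seed <- (config$seed %% 2^31) + 7919 * k
    init_k <- chain_init(model_spec, n_pars, chain_seed, init, k)
    res <- hz_nuts_chain(
      model_spec, init_k, config$n_iter, config$n_warmup, config$thin,
      config$target_accept, config$max_treedepth, chain_seed
    )
    draws_k <- transform(res$draws)
    chains[[k]] <- draws_k
    divergences[k] <- res$n_divergent
    step_sizes[k] <- res$step_size
    accept[k] <- res$accept_mean
    depth[k] <- res$treedepth_mean
  }
  d_out <- ncol(chains[[1]])
  par_names <- par_names %||% colnames(chains[[1]]) %||%
    paste0("par", seq_len(d_out))
  draws <- array(NA_real_, c(n_keep, config$n_chains, d_out),
    dimnames = list(NULL, NULL, par_names)
  )
  for (k in seq_len(config$n_chains)) draws[, k, ] <- chains[[k]]
  if (sum(divergences) > 0.1 * n_keep * config$n_chains) {
    warning(sprintf(
      "%.1f%% divergent transitions; estimates may be unreliable",
      100 * sum(divergences) / (n_keep * config$n_chains)
    ))
  }
  structure(
    list(
      draws = draws, divergences = divergences, config = config,
      step_size = step_sizes, accept_mean = accept, treedepth_mean = depth
    ),
    class = "hz_draws"
  )
}

chain_init <- function(model_spec, n_pars, chain_seed, init, k) {
  if (!is.null(init)) {
    v <- if (is.list(init)) init[[k]] else init
    stopifnot(length(v) == n_pars)
    return(as.numeric(v))
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE
  )
  set.seed(chain_seed)
  for (try in seq_len(100)) {
    q0 <- runif(n_pars, -2, 2)
    lp <- hz_model_logp(model_spec, q0)$value
    if (is.finite(lp)) return(q0)
  }
  stop("could not find a finite initial log density after 100 attempts")
}

#' @export
print.hz_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(
    "<posterior draws: %d iterations x %d chains x %d parameters; %d divergent>\n",
    d[1], d[2], d[3], sum(x$divergences)
  ))
  invisible(x)
}

n_draws <- function(x) dim(x$draws)[1] * dim(x$draws)[2]

# parameter draws as iterations x chains matrix
par_matrix <- function(x, name) x$draws[, , name, drop = TRUE]

# all draws for a parameter, flattened chains-first-kept-order
par_vector <- function(x, name) as.vector(x$draws[, , name])
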