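#' MCMC configuration
#'
#' Sampler settings shared by the three inference stages. Defaults mirror
#' the reference analysis settings for hierarchical estimation: 3 chains,
#' 2000 burn-in and 4000 retained draws per chain; the comparison and
#' mixture stages construct their own defaults (see [fit_product_space()]
#' and [fit_latent_mixture()]). A seed is mandatory so every reported run
#' is reproducible.
#'
#' @param chains number of chains (>= 2, required by the convergence
#'   diagnostic).
#' @param burnin discarded draws per chain.
#' @param draws retained draws per chain.
#' @param seed integer RNG seed (mandatory).
#' @param rhat_threshold convergence threshold on split-chain R-hat
#'   (default 1.05).
#' @return a list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, burnin = 2000, draws = 4000, seed = 1,
                        rhat_threshold = 1.05) {
  if (is.null(seed) || is.na(seed)) stop("a seed is mandatory")
  if (chains < 2) stop("at least 2 chains are required for diagnostics")
  if (burnin < 0 || draws < 1) stop("burnin must be >= 0 and draws >= 1")
  structure(list(chains = as.integer(chains), burnin = as.integer(burnin),
                 draws = as.integer(draws), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold),
            class = "mcmc_config")
}

dataset_to_lists <- function(dataset) {
  list(decks = lapply(dataset$participants, `[[`, "deck"),
       nets = lapply(dataset$participants, net_outcomes))
}

hier_param_names <- function(ids) {
  c(paste0("mu_", c("A", "w", "a", "c")),
    paste0("sigma_", c("A", "w", "a", "c")),
    as.vector(t(outer(ids, c("A", "w", "a", "c"),
                      function(i, p) paste0("z_", p, "[", i, "]")))))
}

#' Fit the hierarchical PVL-Delta model to one group
#'
#' Samples the joint posterior of the group-level means `mu_z'` (standard
#' normal priors), group-level SDs `sigma_z'` (uniform priors on
#' (0, 1.5)), and the individual probit-scale parameters `z'_i` (normal
#' within-group priors), with the PVL-Delta choice likelihood. The sampler
#' is an adaptive Metropolis-within-Gibbs scheme with conjugate updates for
#' the group means; split-chain R-hat is computed for every parameter and
#' the fit is flagged (with a warning) when any exceeds the configured
#' threshold.
#'
#' @param dataset an `igt_dataset` with at least 2 participants.
#' @param config an [mcmc_config()].
#' @param outcome_scale utility scaling divisor (default 100).
#' @param likelihood set `FALSE` to switch the choice likelihood off and
#'   sample the prior (used for prior-calibration checks).
#' @return object of class `igt_hfit` with elements `draws`
#'   (chain x iteration x parameter array), `rhat`, `converged`, `ids`,
#'   `config`, `outcome_scale`.
#' @examples
#' \donttest{
#' set.seed(1)
#' sim <- generate_group_dataset(rep(0, 4), rep(0.3, 4), n_participants = 4,
#'                               n_trials = 30, seed = 1)
#' fit <- fit_hierarchical_group(sim$dataset,
#'                               mcmc_config(chains = 2, burnin = 100,
#'                                           draws = 200, seed = 1))
#' }
#' @export
fit_hierarchical_group <- function(dataset, config = mcmc_config(),
                                   outcome_scale = 100, likelihood = TRUE) {
  stopifnot(inherits(dataset, "igt_dataset"), inherits(config, "mcmc_config"))
  if (length(dataset) < 2) stop("hierarchical fitting needs >= 2 participants")
  if (any(vapply(dataset$participants, function(p) length(p$deck), integer(1)) < 1))
    stop("every participant needs >= 1 trial")
  dat <- dataset_to_lists(dataset)
  set.seed(config$seed)
  res <- fit_hier_cpp(dat$decks, dat$nets, config$chains, config$burnin,
                      config$draws, likelihood, outcome_scale, 1.5)
  draws <- res$draws
  ids <- vapply(dataset$participants, `[[`, character(1), "id")
  dimnames(draws) <- list(NULL, NULL, hier_param_names(ids))
  rhat <- gelman_rubin(draws)
  converged <- all(rhat < config$rhat_threshold, na.rm = FALSE) &&
    !anyNA(rhat)
  if (!isTRUE(converged))
    warning("fit flagged as not converged: max R-hat = ",
            round(max(rhat, na.rm = TRUE), 4),
            if (anyNA(rhat)) " (some R-hat undefined)")
  structure(
    list(draws = draws, rhat = rhat, converged = converged, ids = ids,
         n_participants = length(ids), dataset_name = dataset$name,
         config = config, outcome_scale = outcome_scale,
         likelihood = likelihood),
    class = "igt_hfit"
  )
}

#' @export
print.igt_hfit <- function(x, ...) {
  cat("Hierarchical PVL-Delta fit: '", x$dataset_name, "' (",
      x$n_participants, " participants)\n", sep = "")
  cat(x$config$chains, "chains x", x$config$draws, "retained draws; max R-hat =",
      round(max(x$rhat, na.rm = TRUE), 4),
      if (x$converged) "(converged)\n" else "(NOT converged)\n")
  print(utils::head(posterior_summary(x), 8))
  cat("...\n")
  invisible(x)
}

#' Posterior summary table
#'
#' @param fit an `igt_hfit`.
#' @param params optional character vector restricting the parameters.
#' @return data frame with posterior mean, SD, central 95% interval and
#'   R-hat per parameter.
#' @export
posterior_summary <- function(fit, params = NULL) {
  stopifnot(inherits(fit, "igt_hfit"))
  nm <- dimnames(fit$draws)[[3]]
  if (is.null(params)) params <- nm
  out <- do.call(rbind, lapply(params, function(p) {
    x <- as.vector(fit$draws[, , p])
    q <- stats::quantile(x, c(0.025, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               q2.5 = q[1], q97.5 = q[2], rhat = unname(fit$rhat[p]))
  }))
  rownames(out) <- NULL
  out
}

#' Individual-level posterior point estimates on the natural scale
#'
#' Default (`average = "probit"`): posterior means are taken on the probit
#' scale and then transformed to the natural ranges (the documented choice
#' for downstream post hoc fitting); `average = "natural"` instead averages
#' the draw-wise natural-scale values.
#'
#' @param fit an `igt_hfit`.
#' @param average `"probit"` (default) or `"natural"`.
#' @return matrix (participants x 4) of natural-scale `A, w, a, c`, row
#'   names the participant ids.
#' @export
individual_posterior_params <- function(fit, average = c("probit", "natural")) {
  stopifnot(inherits(fit, "igt_hfit"))
  average <- match.arg(average)
  n <- fit$n_participants
  out <- matrix(NA_real_, n, 4, dimnames = list(fit$ids, c("A", "w", "a", "c")))
  for (i in seq_len(n)) {
    cols <- paste0("z_", c("A", "w", "a", "c"), "[", fit$ids[i], "]")
    zm <- sapply(cols, function(p) as.vector(fit$draws[, , p]))
    if (average == "probit") {
      out[i, ] <- probit_matrix_to_natural(matrix(colMeans(zm), 1))
    } else {
      out[i, ] <- colMeans(probit_matrix_to_natural(zm))
    }
  }
  out
}

#' Export posterior draws as tidy CSV
#'
#' One row per (chain, iteration, parameter) triple.
#'
#' @param fit an `igt_hfit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_draws_csv <- function(fit, path) {
  stopifnot(inherits(fit, "igt_hfit"))
  d <- fit$draws
  nm <- dimnames(d)[[3]]
  long <- data.frame(
    chain = rep(seq_len(dim(d)[1]), times = dim(d)[2] * dim(d)[3]),
    iteration = rep(rep(seq_len(dim(d)[2]), each = dim(d)[1]), times = dim(d)[3]),
    parameter = rep(nm, each = dim(d)[1] * dim(d)[2]),
    value = as.vector(d))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Export a posterior summary as JSON
#'
#' Writes per-parameter mean, sd, central 95% interval and R-hat, plus
#' provenance (package version, sampler configuration, seed).
#'
#' @param fit an `igt_hfit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_summary_json <- function(fit, path) {
  stopifnot(inherits(fit, "igt_hfit"))
  s <- posterior_summary(fit)
  payload <- list(
    provenance = run_provenance(fit$config),
    dataset = fit$dataset_name,
    outcome_scale = fit$outcome_scale,
    converged = fit$converged,
    parameters = s
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

run_provenance <- function(config = NULL) {
  out <- list(package = "igtbayes",
              version = as.character(utils::packageVersion("igtbayes")))
  if (!is.null(config)) out$config <- unclass(config)
  out
}
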