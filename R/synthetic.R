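#' Generate a synthetic group of PVL-Delta agents
#'
#' Draws each participant's probit-scale parameters from
#' `N(mu_probit, sigma_probit)`, transforms them to the natural ranges, and
#' simulates IGT play under the given payoff scheme. One master seed spawns
#' a deterministic per-participant stream, so participant `i`'s data are
#' identical whenever `(seed, i)` match, regardless of `n_participants`.
#'
#' @param mu_probit length-4 group-level means on the probit scale
#'   (A, w, a, c).
#' @param sigma_probit length-4 group-level SDs (`>= 0`; 0 gives identical
#'   individuals).
#' @param n_participants group size.
#' @param n_trials trials per participant (default 100).
#' @param scheme an `igt_scheme` (default traditional).
#' @param seed master seed (mandatory).
#' @param group group label attached to every participant.
#' @param id_prefix prefix for participant ids.
#' @param outcome_scale utility scaling divisor used by the agents
#'   (default 100); must match the value used at fitting time.
#' @return list with `dataset` (an `igt_dataset`) and `truth` (class
#'   `igt_truth`: hyperparameters, per-participant natural and probit
#'   parameters, and the design).
#' @examples
#' sim <- generate_group_dataset(rep(0, 4), rep(0.3, 4), 5, 20, seed = 42)
#' sim$truth$params
#' @export
generate_group_dataset <- function(mu_probit, sigma_probit, n_participants,
                                   n_trials = 100,
                                   scheme = traditional_scheme(), seed,
                                   group = "group", id_prefix = "p",
                                   outcome_scale = 100) {
  stopifnot(length(mu_probit) == 4, length(sigma_probit) == 4)
  if (any(sigma_probit < 0)) stop("sigma_probit must be >= 0")
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  if (n_participants < 1) stop("n_participants must be >= 1")
  zmat <- matrix(NA_real_, n_participants, 4)
  parts <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    set.seed(participant_seed(seed, i))
    zmat[i, ] <- stats::rnorm(4, mu_probit, sigma_probit)
    nat <- probit_matrix_to_natural(zmat[i, , drop = FALSE])
    parts[[i]] <- simulate_pvl_agent(
      pvl_params(nat[1, "A"], nat[1, "w"], nat[1, "a"], nat[1, "c"]),
      scheme = scheme, n_trials = n_trials,
      id = sprintf("%s%02d", id_prefix, i), outcome_scale = outcome_scale,
      group = group)
  }
  nat_all <- probit_matrix_to_natural(zmat)
  rownames(nat_all) <- rownames(zmat) <-
    vapply(parts, `[[`, character(1), "id")
  truth <- structure(
    list(mu_probit = stats::setNames(mu_probit, c("A", "w", "a", "c")),
         sigma_probit = stats::setNames(sigma_probit, c("A", "w", "a", "c")),
         params = nat_all, probit = zmat,
         design = list(n_participants = n_participants, n_trials = n_trials,
                       seed = seed, outcome_scale = outcome_scale),
         group = group),
    class = "igt_truth")
  list(dataset = group_dataset(parts, name = group), truth = truth)
}

# deterministic per-participant sub-seed, kept below 2^31
participant_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2011L + i * 7919L
}

#' Generate a two-group synthetic study
#'
#' Builds two groups with [generate_group_dataset()] and pools them into a
#' single dataset with the group labels *withheld* (for blind latent-mixture
#' evaluation); the labels and full ground truth are returned separately.
#' The default design mirrors a 19 + 19 participant study with 100 trials
#' each.
#'
#' @param mu1,sigma1,mu2,sigma2 probit-scale hyperparameters per group.
#' @param n_per_group length-2 group sizes (default `c(19, 19)`).
#' @param n_trials trials per participant (default 100).
#' @param scheme an `igt_scheme`.
#' @param seed master seed.
#' @param outcome_scale utility scaling divisor (default 100).
#' @return list with `group1`, `group2` (labelled `igt_dataset`s), `pooled`
#'   (labels stripped), `labels` (1/2 in pooled order), and `truth1`,
#'   `truth2`.
#' @export
generate_two_group_study <- function(mu1, sigma1, mu2, sigma2,
                                     n_per_group = c(19, 19), n_trials = 100,
                                     scheme = traditional_scheme(), seed,
                                     outcome_scale = 100) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  g1 <- generate_group_dataset(mu1, sigma1, n_per_group[1], n_trials, scheme,
                               seed = seed, group = "group1",
                               id_prefix = "g1p", outcome_scale = outcome_scale)
  g2 <- generate_group_dataset(mu2, sigma2, n_per_group[2], n_trials, scheme,
                               seed = (as.integer(seed) + 500009L) %%
                                 .Machine$integer.max,
                               group = "group2", id_prefix = "g2p",
                               outcome_scale = outcome_scale)
  blind <- lapply(c(g1$dataset$participants, g2$dataset$participants),
                  function(p) { p$group <- NULL; p })
  list(group1 = g1$dataset, group2 = g2$dataset,
       pooled = group_dataset(blind, name = "pooled"),
       labels = rep(1:2, times = n_per_group),
       truth1 = g1$truth, truth2 = g2$truth)
}

#' Recovery report for a hierarchical fit of synthetic data
#'
#' Compares a fit against the generating ground truth: per group-level
#' parameter (probit scale) the truth, posterior mean, SD, central 95%
#' interval, bias, and a coverage indicator; plus the RMSE of individual
#' posterior means against the true individual probit parameters.
#'
#' @param truth an `igt_truth` from [generate_group_dataset()].
#' @param fit an `igt_hfit` of the corresponding dataset.
#' @return object of class `igt_recovery` with `group_level` (data frame)
#'   and `individual_rmse` (named by parameter).
#' @export
recovery_report <- function(truth, fit) {
  stopifnot(inherits(truth, "igt_truth"), inherits(fit, "igt_hfit"))
  if (fit$n_participants != truth$design$n_participants)
    stop("fit and truth have different numbers of participants")
  pars <- c("A", "w", "a", "c")
  rows <- list()
  for (lvl in c("mu", "sigma")) {
    tr <- if (lvl == "mu") truth$mu_probit else truth$sigma_probit
    s <- posterior_summary(fit, paste0(lvl, "_", pars))
    rows[[lvl]] <- data.frame(
      parameter = s$parameter, truth = unname(tr), post_mean = s$mean,
      post_sd = s$sd, q2.5 = s$q2.5, q97.5 = s$q97.5,
      bias = s$mean - unname(tr),
      covered = as.integer(tr >= s$q2.5 & tr <= s$q97.5))
  }
  group_level <- do.call(rbind, rows)
  rownames(group_level) <- NULL
  # individual-level RMSE on the probit scale
  rmse <- vapply(seq_along(pars), function(j) {
    est <- vapply(fit$ids, function(id) {
      mean(fit$draws[, , paste0("z_", pars[j], "[", id, "]")])
    }, numeric(1))
    sqrt(mean((est - truth$probit[fit$ids, j])^2))
  }, numeric(1))
  names(rmse) <- pars
  structure(list(group_level = group_level, individual_rmse = rmse),
            class = "igt_recovery")
}

#' @export
print.igt_recovery <- function(x, ...) {
  cat("Parameter recovery (probit scale):\n")
  print(cbind(x$group_level[, c("parameter", "truth")],
              round(x$group_level[, c("post_mean", "bias")], 3),
              covered = x$group_level$covered), row.names = FALSE)
  cat("Individual-level RMSE:", paste(names(x$individual_rmse),
                                      round(x$individual_rmse, 3),
                                      sep = "=", collapse = ", "), "\n")
  invisible(x)
}
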