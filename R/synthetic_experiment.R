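# Factorial experiment designs and simulated response tables for testing
# the heteroscedastic inference chain.

#' Balanced factorial experiment design
#'
#' The standard assembly design: four community treatments (three
#' monocultures HD, HU, CV and the three-species mixture Mix) crossed with
#' two core shapes (square aquaria for profile imaging, circular cores for
#' CT), with equal replication in every cell.
#'
#' @param treatments treatment labels.
#' @param core_shapes core shape labels.
#' @param replicates replicates per treatment x shape cell (>= 2).
#' @param seed integer seed used by \code{\link{make_experiment}}.
#' @return Object of class \code{"experiment_design"}.
#' @export
experiment_design <- function(treatments = c("HD", "HU", "CV", "Mix"),
                              core_shapes = c("square", "circular"),
                              replicates = 5L, seed = 1L) {
  stopifnot(length(treatments) >= 1, length(core_shapes) >= 1,
            replicates >= 2)
  structure(list(treatments = treatments, core_shapes = core_shapes,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "experiment_design")
}

#' Simulate a tidy experiment response table
#'
#' One row per aquarium: group mean plus Normal noise with a group-specific
#' standard deviation, emulating the heteroscedasticity observed across
#' species treatments.  Defaults are on the bromide-drawdown scale: species
#' means reconstructed from the strongest irrigator's printed mean
#' (-486.79 mg L^-1) and the printed treatment contrasts, an additive core
#' shape effect (circular cores irrigate more), and residual sds decreasing
#' from the strongest to the weakest irrigator.
#'
#' @param design an \code{\link{experiment_design}}.
#' @param sigma_by_group named vector of residual sds per treatment (all > 0).
#' @param mu_by_group named vector of treatment means.
#' @param shape_effect additive offset applied as +effect/2 to the second
#'   core shape and -effect/2 to the first (0 when only one shape).
#' @param response_name label recorded in the \code{response_name} column.
#' @return data.frame: \code{aquarium_id, treatment, core_shape, replicate,
#'   response, response_name}.
#' @examples
#' d <- make_experiment(experiment_design(seed = 7))
#' nrow(d)  # 4 treatments x 2 shapes x 5 replicates
#' @export
make_experiment <- function(design = experiment_design(),
                            sigma_by_group = c(HD = 230, HU = 120,
                                               CV = 120, Mix = 100),
                            mu_by_group = c(HD = -486.79, HU = -346.90,
                                            CV = -383.42, Mix = -359.83),
                            shape_effect = -312,
                            response_name = "delta_br_mgL") {
  stopifnot(inherits(design, "experiment_design"))
  if (!all(design$treatments %in% names(sigma_by_group))) {
    stop("sigma_by_group must cover every treatment")
  }
  if (!all(design$treatments %in% names(mu_by_group))) {
    stop("mu_by_group must cover every treatment")
  }
  if (any(sigma_by_group[design$treatments] <= 0)) {
    stop("group sds must be positive")
  }
  set.seed(derive_seed(design$seed, 303L))
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      core_shape = design$core_shapes,
                      treatment = design$treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ns <- length(design$core_shapes)
  shape_dev <- if (ns > 1) {
    (match(grid$core_shape, design$core_shapes) - (ns + 1) / 2) /
      (ns - 1) * shape_effect
  } else 0
  mu <- mu_by_group[grid$treatment] + shape_dev
  sdv <- sigma_by_group[grid$treatment]
  data.frame(aquarium_id = sprintf("%s_%s_%02d", grid$treatment,
                                   substr(grid$core_shape, 1, 2),
                                   grid$replicate),
             treatment = grid$treatment,
             core_shape = grid$core_shape,
             replicate = grid$replicate,
             response = rnorm(nrow(grid), mu, sdv),
             response_name = response_name,
             stringsAsFactors = FALSE)
}
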