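# Simulation-plan accounting: tabulate protocols and total simulated time.
# The hydration protocol (2 ns equilibration + 20 ns production per site,
# eight receptors, two sites) totals 352 ns; together with the pure-water
# simulations (3 x 40 ns per receptor) and the stated cumulative cosolvent
# time of 1.2 us per receptor the whole campaign exceeds 10 us.

#' Build a simulation plan
#'
#' @param protocol protocol label per entry.
#' @param receptor receptor label per entry.
#' @param target site or probe label per entry.
#' @param replicates replicate count per entry.
#' @param equil_ns,prod_ns equilibration and production length per
#'   replicate, nanoseconds.
#' @return data frame of class `simulation_plan`.
#' @export
simulation_plan <- function(protocol, receptor, target, replicates,
                            equil_ns, prod_ns) {
  plan <- data.frame(protocol = protocol, receptor = receptor,
                     target = target, replicates = as.integer(replicates),
                     equil_ns = as.numeric(equil_ns),
                     prod_ns = as.numeric(prod_ns))
  if (any(plan$equil_ns < 0 | plan$prod_ns < 0 | plan$replicates < 0))
    stop("replicate counts and durations must be >= 0")
  class(plan) <- c("simulation_plan", class(plan))
  plan
}

#' Total simulated time of a plan
#'
#' @param plan a [simulation_plan()] (plans rbind cleanly).
#' @return total nanoseconds: sum of
#'   `replicates * (equil_ns + prod_ns)`.
#' @export
plan_total_time <- function(plan) {
  if (!nrow(plan)) stop("empty simulation plan")
  sum(plan$replicates * (plan$equil_ns + plan$prod_ns))
}

DEFAULT_RECEPTORS <- c("AR", "ERa", "ERb", "GR", "MR", "PR", "TRa", "TRb")

#' Hydration-site simulation plan
#'
#' One restrained simulation per receptor and site.
#'
#' @param receptors receptor labels (default: the eight-receptor panel).
#' @param sites site labels.
#' @param equil_ns,prod_ns per-simulation durations (defaults 2 + 20 ns).
#' @return a [simulation_plan()].
#' @export
hydration_site_plan <- function(receptors = DEFAULT_RECEPTORS,
                                sites = c("AF2", "BF3"),
                                equil_ns = 2, prod_ns = 20) {
  grid <- expand.grid(receptor = receptors, target = sites,
                      stringsAsFactors = FALSE)
  simulation_plan("hydration", grid$receptor, grid$target,
                  replicates = 1L, equil_ns = equil_ns, prod_ns = prod_ns)
}

#' Pure-water simulation plan
#'
#' @param receptors receptor labels.
#' @param replicates independent runs per receptor (default 3).
#' @param prod_ns production length per run (default 40 ns).
#' @return a [simulation_plan()].
#' @export
pure_water_plan <- function(receptors = DEFAULT_RECEPTORS,
                            replicates = 3L, prod_ns = 40) {
  simulation_plan("pure_water", receptors, "LBD", replicates,
                  equil_ns = 0, prod_ns = prod_ns)
}

#' Cosolvent simulation plan
#'
#' The cumulative cosolvent time per receptor is taken as an input rather
#' than derived from a run-count decomposition (probe count, runs per
#' probe and apo/holo variants are campaign choices, not fixed here).
#'
#' @param receptors receptor labels.
#' @param ns_per_receptor cumulative cosolvent simulation time per
#'   receptor, nanoseconds (default 1200).
#' @return a [simulation_plan()].
#' @export
cosolvent_plan <- function(receptors = DEFAULT_RECEPTORS,
                           ns_per_receptor = 1200) {
  simulation_plan("cosolvent", receptors, "IPA+ACN+PYR", replicates = 1L,
                  equil_ns = 0, prod_ns = ns_per_receptor)
}
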