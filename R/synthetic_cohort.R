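# Multi-animal dose-group cohorts with programmed regional depletion
# fractions, emulating the n = 6/group (3 male, 3 female) multi-region
# design of antibody-mediated microglia depletion studies.

#' Design of a synthetic depletion cohort
#'
#' Declares treatment groups, brain regions with baseline microglia density,
#' and the programmed depletion fraction of each group in each region.
#' Exactly one group must be the control, with zero depletion everywhere.
#'
#' @param groups data frame with columns `group` (name), `n_animals`
#'   (>= 2), and logical `control` (exactly one `TRUE`).
#' @param regions data frame with columns `region` (name),
#'   `baseline_density` (cells/mm^3, > 0) and `cv` (between-animal
#'   coefficient of variation, >= 0).
#' @param depletion data frame with columns `group`, `region`,
#'   `fraction` in `[0, 1)`; omitted pairs default to 0. The control group
#'   must have fraction 0 in all regions.
#' @return an `experiment_design` list.
#' @examples
#' des <- experiment_design(
#'   groups = data.frame(group = c("control", "anti-CSF1"),
#'                       n_animals = 6, control = c(TRUE, FALSE)),
#'   regions = data.frame(region = c("fimbria", "cortex"),
#'                        baseline_density = c(3000, 2000), cv = 0.10),
#'   depletion = data.frame(group = "anti-CSF1", region = "fimbria",
#'                          fraction = 0.65))
#' @export
experiment_design <- function(groups, regions, depletion = NULL) {
  stopifnot(is.data.frame(groups), is.data.frame(regions))
  if (!all(c("group", "n_animals", "control") %in% names(groups)))
    bad_arg("groups", "needs columns group, n_animals, control")
  if (!all(c("region", "baseline_density", "cv") %in% names(regions)))
    bad_arg("regions", "needs columns region, baseline_density, cv")
  if (sum(groups$control) != 1L)
    bad_arg("groups", "exactly one group must be flagged control")
  if (any(groups$n_animals < 2L))
    bad_arg("groups", "every group needs n_animals >= 2")
  if (anyDuplicated(groups$group)) bad_arg("groups", "duplicate group names")
  if (anyDuplicated(regions$region)) bad_arg("regions", "duplicate regions")
  if (any(regions$baseline_density <= 0))
    bad_arg("regions", "baseline_density must be > 0")
  if (any(regions$cv < 0)) bad_arg("regions", "cv must be >= 0")

  # full group x region depletion table, defaulting to 0
  dep <- expand.grid(group = groups$group, region = regions$region,
                     stringsAsFactors = FALSE)
  dep$fraction <- 0
  if (!is.null(depletion)) {
    if (!all(c("group", "region", "fraction") %in% names(depletion)))
      bad_arg("depletion", "needs columns group, region, fraction")
    for (i in seq_len(nrow(depletion))) {
      j <- which(dep$group == depletion$group[i] &
                 dep$region == depletion$region[i])
      if (length(j) != 1L)
        bad_arg("depletion", sprintf("unknown group/region pair '%s'/'%s'",
                                     depletion$group[i], depletion$region[i]))
      dep$fraction[j] <- depletion$fraction[i]
    }
  }
  if (any(dep$fraction < 0 | dep$fraction >= 1))
    bad_arg("depletion", "fractions must be in [0, 1)")
  ctrl <- groups$group[groups$control]
  if (any(dep$fraction[dep$group == ctrl] != 0))
    bad_arg("depletion", "control group must have zero depletion everywhere")

  structure(list(groups = groups, regions = regions, depletion = dep,
                 control = ctrl),
            class = "experiment_design")
}

#' Generate a per-animal, per-region density cohort table
#'
#' For each animal and region, the expected density is
#' `baseline * (1 - depletion_fraction)` multiplied by lognormal
#' between-animal noise with the region's coefficient of variation (mean
#' preserved, i.e. `meanlog = -sdlog^2 / 2`). Sexes alternate M/F within
#' each group as metadata; no sex effect is generated unless
#' `sex_effect` is given (a multiplicative factor applied to female
#' densities). Pure function of `(design, seed)`.
#'
#' @param design an [experiment_design()].
#' @param seed integer seed.
#' @param stack_volume_mm3 imaged volume per animal used to convert density
#'   to an expected cell count per stack (default: the volume of the default
#'   [stack_spec()] geometry).
#' @param sex_effect multiplicative factor on female expected density
#'   (default 1: no sex effect).
#' @return a `cohort` data frame: `animal_id`, `group`, `sex`, `region`,
#'   `density` (cells/mm^3) and `expected_count` (cells in
#'   `stack_volume_mm3`), with attribute `control` naming the control group.
#' @export
generate_cohort <- function(design, seed,
                            stack_volume_mm3 = NULL,
                            sex_effect = 1) {
  stopifnot(inherits(design, "experiment_design"))
  if (is.null(stack_volume_mm3)) {
    sp <- stack_spec()
    stack_volume_mm3 <- prod(sp$shape_xyz * c(sp$voxel_xy, sp$voxel_xy,
                                              sp$voxel_z)) / 1e9
  }
  with_seed(seed, {
    rows <- list()
    for (gi in seq_len(nrow(design$groups))) {
      g <- design$groups$group[gi]
      n <- design$groups$n_animals[gi]
      sexes <- rep(c("M", "F"), length.out = n)
      for (ai in seq_len(n)) {
        id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "-", g), ai)
        for (ri in seq_len(nrow(design$regions))) {
          reg <- design$regions$region[ri]
          frac <- design$depletion$fraction[design$depletion$group == g &
                                            design$depletion$region == reg]
          mu <- design$regions$baseline_density[ri] * (1 - frac)
          if (sexes[ai] == "F") mu <- mu * sex_effect
          cv <- design$regions$cv[ri]
          dens <- if (cv > 0) {
            sdlog <- sqrt(log(1 + cv^2))
            mu * rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
          } else mu
          rows[[length(rows) + 1L]] <- data.frame(
            animal_id = id, group = g, sex = sexes[ai], region = reg,
            density = dens, expected_count = dens * stack_volume_mm3)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "control") <- design$control
    class(out) <- c("cohort", "data.frame")
    out
  })
}
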