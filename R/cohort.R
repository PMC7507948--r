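# Synthetic canine cohorts.
#
# Emulates a five-group carbon tetrachloride (CCl4) fibrosis study: five
# animals per group by default (Control, CCl4 1-4 months), each with
# per-vessel diameters and maximum velocities, blood properties, and an
# invasive free portal pressure (FPP) ground truth.  All quantities are
# drawn independently from group-level Normal(mean, SD) distributions
# truncated below at 0.2 x mean; disease-stage correlation is carried by
# group membership alone.

.VESSELS6 <- c("portal_vein", "left_portal", "right_portal",
               "splenic", "superior_mesenteric", "inferior_mesenteric")

.GROUPS <- c("Control", "CCl4_1mo", "CCl4_2mo", "CCl4_3mo", "CCl4_4mo")

# group-level means and SDs: FPP (mmHg), vessel diameters (mm), maximum
# velocities (cm/s); columns follow .GROUPS order.
.FPP_TAB <- rbind(mean = c(6.6, 10.0, 13.6, 15.6, 19.2),
                  sd   = c(1.1,  1.6,  1.5,  4.0,  1.9))
.DIAM_TAB <- list(
  mean = rbind(portal_vein         = c(4.5, 7.2, 7.7, 8.2, 9.5),
               left_portal         = c(3.4, 4.9, 5.9, 6.2, 7.6),
               right_portal        = c(4.2, 4.9, 5.2, 5.8, 6.8),
               splenic             = c(1.8, 3.4, 4.0, 4.5, 4.9),
               superior_mesenteric = c(3.1, 4.1, 4.8, 5.8, 6.0),
               inferior_mesenteric = c(2.0, 2.4, 2.9, 3.5, 3.8)),
  sd   = rbind(portal_vein         = c(0.4, 0.6, 1.2, 1.0, 1.3),
               left_portal         = c(0.3, 0.7, 0.9, 1.4, 1.2),
               right_portal        = c(0.2, 0.4, 0.6, 0.6, 1.2),
               splenic             = c(0.2, 0.5, 0.5, 0.7, 0.8),
               superior_mesenteric = c(0.3, 0.2, 0.5, 0.7, 0.6),
               inferior_mesenteric = c(0.1, 0.3, 0.3, 0.4, 0.4)))
.VEL_TAB <- list(
  mean = rbind(portal_vein         = c(33.8, 30.6, 24.8, 25.1, 22.0),
               left_portal         = c(22.6, 23.2, 13.7, 11.4,  9.7),
               right_portal        = c(24.2, 25.4, 14.5, 11.7, 10.6),
               splenic             = c(16.5, 16.5, 13.8, 18.5, 13.7),
               superior_mesenteric = c(27.3, 27.5, 18.0, 17.7, 16.5),
               inferior_mesenteric = c(15.0, 13.0, 10.7, 11.1, 10.3)),
  sd   = rbind(portal_vein         = c(8.7, 6.3, 3.7, 1.5, 1.6),
               left_portal         = c(4.4, 2.9, 3.4, 2.3, 0.5),
               right_portal        = c(4.2, 1.3, 4.9, 2.1, 0.6),
               splenic             = c(2.3, 2.0, 2.9, 6.5, 2.2),
               superior_mesenteric = c(4.3, 4.5, 0.9, 2.3, 3.0),
               inferior_mesenteric = c(1.6, 1.6, 1.8, 1.1, 0.5)))

#' Default group parameters of the fibrosis study
#'
#' Returns the five experimental groups (Control and CCl4 at 1-4 months of
#' dosing) with the study's per-group mean +/- SD of invasive FPP, the six
#' portal-system vessel diameters, and their maximum Doppler velocities.
#' Blood density (1050 +/- 15 kg/m^3) and viscosity (3.5e-3 +/- 0.3e-3 Pa s)
#' are typical mammalian whole-blood values, identical across groups; they
#' were not staged by the study design.
#'
#' @return list of five \code{group_params} objects; each has elements
#'   \code{group}, \code{fpp} (c(mean, sd), mmHg), \code{diameter} and
#'   \code{velocity} (6 x 2 matrices, mm and cm/s), \code{rho}, \code{mu}.
#' @examples
#' p <- default_group_params()
#' p[[1]]$fpp       # Control FPP: 6.6 +/- 1.1 mmHg
#' @export
default_group_params <- function() {
  lapply(seq_along(.GROUPS), function(g) {
    structure(list(
      group = .GROUPS[g],
      fpp = c(mean = unname(.FPP_TAB["mean", g]),
              sd = unname(.FPP_TAB["sd", g])),
      diameter = cbind(mean = .DIAM_TAB$mean[, g], sd = .DIAM_TAB$sd[, g]),
      velocity = cbind(mean = .VEL_TAB$mean[, g], sd = .VEL_TAB$sd[, g]),
      rho = c(mean = 1050, sd = 15),
      mu = c(mean = 3.5e-3, sd = 0.3e-3)),
      class = "group_params")
  })
}

validate_group_params <- function(params) {
  if (!length(params)) pf_stop("empty group parameter list", "pf_config_error")
  for (p in params) {
    vals <- c(p$fpp["mean"], p$diameter[, "mean"], p$velocity[, "mean"],
              p$rho["mean"], p$mu["mean"])
    sds <- c(p$fpp["sd"], p$diameter[, "sd"], p$velocity[, "sd"],
             p$rho["sd"], p$mu["sd"])
    if (any(vals <= 0)) pf_stop("group means must be > 0", "pf_config_error")
    if (any(sds < 0)) pf_stop("group SDs must be >= 0", "pf_config_error")
  }
  invisible(TRUE)
}

#' Generate a synthetic cohort
#'
#' Draws \code{n_per_group} animals per group.  Every quantity is an
#' independent Normal(mean, SD) draw truncated below at 0.2 x mean; each
#' animal consumes its own seeded substream, so cohorts are a pure function
#' of (params, n, seed, mode) and adding animals never perturbs earlier
#' draws.
#'
#' Modes: in \code{"table_emulation"} the ground-truth FPP is drawn directly
#' from the group FPP distribution (truth and Doppler measurements are
#' linked only through group membership, as in the real study).  In
#' \code{"forward_consistent"} the FPP draw is used as the animal's absolute
#' reference pressure \code{p_ref} and the truth is produced by
#' \code{\link{forward_truth}}, so that the full pipeline applied to
#' noise-free measurements recovers \code{fpp_true} exactly.
#'
#' @param params list of \code{group_params} (default
#'   \code{\link{default_group_params}()}).
#' @param n_per_group animals per group (>= 1; the study used 5).
#' @param seed integer seed.
#' @param mode "table_emulation" or "forward_consistent".
#' @param tree_template tree supplying topology and segment lengths for
#'   per-animal geometry (default \code{\link{canonical_tree}()}).
#' @param mean_factor mean/max velocity ratio used by the forward model.
#' @return a \code{cohort}: list with data frames \code{animals}
#'   (animal-level) and \code{measurements} (one row per animal-vessel).
#' @export
generate_cohort <- function(params = default_group_params(),
                            n_per_group = 5L, seed = 1L,
                            mode = c("table_emulation", "forward_consistent"),
                            tree_template = canonical_tree(),
                            mean_factor = 0.7) {
  mode <- match.arg(mode)
  validate_group_params(params)
  if (n_per_group < 1L)
    pf_stop("'n_per_group' must be >= 1", "pf_parameter_error")

  n_tot <- length(params) * n_per_group
  ids <- character(n_tot); groups <- character(n_tot)
  rho <- mu <- p_ref <- fpp <- numeric(n_tot)
  dmat <- vmat <- matrix(0, n_tot, length(.VESSELS6),
                         dimnames = list(NULL, .VESSELS6))
  k <- 0L
  for (p in params) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      set.seed(pf_substream(seed, k))
      dmat[k, ] <- pf_rnorm_trunc(nrow(p$diameter), p$diameter[, "mean"],
                                  p$diameter[, "sd"])
      vmat[k, ] <- pf_rnorm_trunc(nrow(p$velocity), p$velocity[, "mean"],
                                  p$velocity[, "sd"])
      rho[k] <- pf_rnorm_trunc(1, p$rho["mean"], p$rho["sd"])
      mu[k] <- pf_rnorm_trunc(1, p$mu["mean"], p$mu["sd"])
      fdraw <- pf_rnorm_trunc(1, p$fpp["mean"], p$fpp["sd"])
      ids[k] <- sprintf("%s_%02d", p$group, i)
      groups[k] <- p$group
      if (mode == "table_emulation") {
        fpp[k] <- fdraw; p_ref[k] <- NA_real_
      } else {
        p_ref[k] <- fdraw; fpp[k] <- NA_real_   # filled below
      }
    }
  }
  animals <- data.frame(animal_id = ids, group = groups, rho = rho, mu = mu,
                        p_ref_mmhg = p_ref, fpp_true_mmhg = fpp,
                        stringsAsFactors = FALSE)
  meas <- data.frame(
    animal_id = rep(ids, each = length(.VESSELS6)),
    group = rep(groups, each = length(.VESSELS6)),
    vessel = rep(.VESSELS6, n_tot),
    d_mm = as.vector(t(dmat)),
    d_us_mm = as.vector(t(dmat)),
    vmax_cm_s = as.vector(t(vmat)),
    direction = "toward_liver",
    stringsAsFactors = FALSE)

  cohort <- structure(list(animals = animals, measurements = meas,
                           seed = seed, mode = mode,
                           n_per_group = n_per_group,
                           tree_template = tree_template,
                           mean_factor = mean_factor),
                      class = "cohort")
  if (mode == "forward_consistent") {
    for (j in seq_len(n_tot)) {
      rec <- get_animal(cohort, ids[j])
      cohort$animals$fpp_true_mmhg[j] <-
        forward_truth(rec, tree_template, p_ref = animals$p_ref_mmhg[j],
                      mean_factor = mean_factor)
    }
  }
  cohort
}

#' Extract one animal record from a cohort
#'
#' @param cohort a \code{cohort}.
#' @param animal_id an id present in \code{cohort$animals}.
#' @return an \code{animal_record}: list with \code{animal_id}, \code{group},
#'   \code{blood} (rho, mu), \code{p_ref_mmhg}, \code{fpp_true_mmhg} and the
#'   per-vessel data frame \code{vessels} (geometry diameter \code{d_mm},
#'   Doppler \code{d_us_mm}, \code{vmax_cm_s}, \code{direction}).
#' @export
get_animal <- function(cohort, animal_id) {
  i <- match(animal_id, cohort$animals$animal_id)
  if (is.na(i)) pf_stop(sprintf("no animal '%s'", animal_id), "pf_config_error")
  a <- cohort$animals[i, ]
  m <- cohort$measurements[cohort$measurements$animal_id == animal_id,
                           c("vessel", "d_mm", "d_us_mm", "vmax_cm_s",
                             "direction")]
  structure(list(animal_id = a$animal_id, group = a$group,
                 blood = list(rho = a$rho, mu = a$mu),
                 p_ref_mmhg = a$p_ref_mmhg,
                 fpp_true_mmhg = a$fpp_true_mmhg,
                 vessels = m),
            class = "animal_record")
}

#' Per-animal vessel tree
#'
#' Instantiates the template topology (and its segment lengths) with this
#' animal's own vessel diameters — the synthetic analogue of reconstructing
#' each subject's geometry from its CT scan.
#'
#' @param record an \code{animal_record}.
#' @param template a \code{vessel_tree} supplying topology and lengths.
#' @return a \code{vessel_tree}.
#' @export
animal_tree <- function(record, template = canonical_tree()) {
  d <- stats::setNames(record$vessels$d_mm, record$vessels$vessel)
  L <- stats::setNames(template$segments$length_mm, template$segments$name)
  canonical_tree(diameters = d, lengths = L)
}

#' Noise-free forward truth for one animal
#'
#' Runs the boundary-condition mapping and network solver on the animal's
#' noise-free measurements and returns \code{p_ref} plus the trunk-midpoint
#' viscous pressure rise, guaranteeing that the full pipeline applied to
#' noise-free data recovers \code{fpp_true} exactly.
#'
#' @param record an \code{animal_record} with a full Doppler set.
#' @param tree tree template (topology + lengths).
#' @param p_ref absolute reference pressure, mmHg.
#' @param mean_factor mean/max velocity ratio.
#' @return ground-truth FPP, mmHg.
#' @export
forward_truth <- function(record, tree = canonical_tree(), p_ref = 0,
                          mean_factor = 0.7) {
  rec <- record
  rec$vessels$d_us_mm <- rec$vessels$d_mm   # noise-free measurements
  atree <- animal_tree(rec, tree)
  cfg <- solver_config(p_ref = p_ref)
  bcs <- assemble_bcs(rec, atree, mean_factor = mean_factor)
  sol <- solve_network(atree, bcs, rec$blood, cfg)
  extract_vfpp(sol, atree, cfg)
}

#' Simulate the gravimetric blood-density protocol
#'
#' Emulates weighing a 1 mL blood aliquot on an electronic balance: at least
#' three repeated noisy weighings are averaged and converted to kg/m^3 (the
#' mass in grams of 1 mL numerically equals the density in g/mL).
#'
#' @param true_density true density, kg/m^3.
#' @param n_repeats number of weighings (protocol floor of 3).
#' @param noise_sd per-weighing noise SD expressed in kg/m^3.
#' @param seed optional seed.
#' @return measured density, kg/m^3 (mean of the repeats).
#' @export
simulate_blood_density <- function(true_density, n_repeats = 3L,
                                   noise_sd = 5, seed = NULL) {
  pf_check_positive(true_density = true_density)
  if (n_repeats < 3L)
    pf_stop("the weighing protocol requires n_repeats >= 3",
            "pf_parameter_error")
  if (noise_sd < 0) pf_stop("'noise_sd' must be >= 0", "pf_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  mean(true_density + stats::rnorm(n_repeats, 0, noise_sd))
}

#' Add Doppler measurement noise
#'
#' Multiplies each measured diameter and maximum velocity by independent
#' Normal(1, cv) factors truncated positive.  Reported intra- and
#' inter-observer variability of the acquisition protocol is below 10%, so
#' defaults keep cv <= 0.10.  Geometry (\code{d_mm}) is untouched: noise is
#' a property of the measurement, not of the vessel.
#'
#' @param record an \code{animal_record} (or a \code{cohort}; then noise is
#'   applied per animal from seeded substreams).
#' @param cv_diameter,cv_velocity coefficients of variation (>= 0).
#' @param seed seed for the perturbation.
#' @return the perturbed object, same class as the input.
#' @export
add_doppler_noise <- function(record, cv_diameter = 0.05, cv_velocity = 0.05,
                              seed = 1L) {
  if (cv_diameter < 0 || cv_velocity < 0)
    pf_stop("noise CVs must be >= 0", "pf_parameter_error")
  if (inherits(record, "cohort")) {
    cohort <- record
    ids <- cohort$animals$animal_id
    for (j in seq_along(ids)) {
      rows <- which(cohort$measurements$animal_id == ids[j])
      set.seed(pf_substream(seed, 100000 + j))
      nv <- length(rows)
      fd <- pf_rnorm_trunc(nv, 1, cv_diameter, lower = .Machine$double.eps)
      fv <- pf_rnorm_trunc(nv, 1, cv_velocity, lower = .Machine$double.eps)
      cohort$measurements$d_us_mm[rows] <-
        cohort$measurements$d_us_mm[rows] * fd
      cohort$measurements$vmax_cm_s[rows] <-
        cohort$measurements$vmax_cm_s[rows] * fv
    }
    return(cohort)
  }
  set.seed(seed)
  nv <- nrow(record$vessels)
  fd <- pf_rnorm_trunc(nv, 1, cv_diameter, lower = .Machine$double.eps)
  fv <- pf_rnorm_trunc(nv, 1, cv_velocity, lower = .Machine$double.eps)
  record$vessels$d_us_mm <- record$vessels$d_us_mm * fd
  record$vessels$vmax_cm_s <- record$vessels$vmax_cm_s * fv
  record
}

#' Serialise a cohort
#'
#' CSV: one row per animal-vessel measurement with the animal-level fields
#' repeated.  JSON: nested per animal.
#'
#' @param cohort a \code{cohort}.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- merge(cohort$measurements,
              cohort$animals[, c("animal_id", "rho", "mu", "fpp_true_mmhg")],
              by = "animal_id", sort = FALSE)
  df <- df[, c("animal_id", "group", "vessel", "d_us_mm", "vmax_cm_s",
               "rho", "mu", "fpp_true_mmhg")]
  names(df)[names(df) == "fpp_true_mmhg"] <- "fpp_true_mmHg"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
write_cohort_json <- function(cohort, path) {
  out <- lapply(cohort$animals$animal_id, function(id) {
    r <- get_animal(cohort, id)
    list(animal_id = r$animal_id, group = r$group,
         rho = r$blood$rho, mu = r$blood$mu,
         p_ref_mmHg = r$p_ref_mmhg, fpp_true_mmHg = r$fpp_true_mmhg,
         doppler = r$vessels)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals (%d per group), mode '%s', seed %d\n",
              nrow(x$animals), x$n_per_group, x$mode, x$seed))
  tab <- tapply(x$animals$fpp_true_mmhg, x$animals$group, mean)
  cat("  group mean FPP (mmHg):\n")
  print(round(tab[unique(x$animals$group)], 2))
  invisible(x)
}
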