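# Per-animal virtual FPP fit: the package's central modelling function.

#' Virtual free portal pressure for one animal
#'
#' Fits the reduced-order flow model to one animal: instantiates the
#' vessel tree with the animal's geometry, maps its Doppler set to
#' mass-balanced boundary conditions, solves the laminar network, and
#' extracts the virtual free portal pressure at the portal-trunk midpoint.
#'
#' @param record an \code{animal_record} (see \code{\link{get_animal}}).
#' @param tree tree template (topology + segment lengths); per-animal
#'   diameters come from the record.
#' @param config a \code{\link{solver_config}}; if \code{p_ref = NULL} in
#'   \code{...} shortcut form, the record's own \code{p_ref_mmhg} is used
#'   when present.
#' @param mean_factor mean/max velocity ratio (default 0.7).
#' @return object of class \code{vfpp_fit} with components \code{vfpp_mmhg},
#'   \code{solution}, \code{bcs}, \code{tree}, \code{record}.
#' @examples
#' coh <- generate_cohort(n_per_group = 1, seed = 7)
#' fit <- vfpp(get_animal(coh, coh$animals$animal_id[1]))
#' coef(fit)
#' @export
vfpp <- function(record, tree = canonical_tree(), config = NULL,
                 mean_factor = 0.7) {
  if (is.null(config)) {
    p_ref <- record$p_ref_mmhg
    if (is.null(p_ref) || is.na(p_ref)) p_ref <- 0
    config <- solver_config(p_ref = p_ref)
  }
  atree <- animal_tree(record, tree)
  bcs <- assemble_bcs(record, atree, mean_factor = mean_factor)
  sol <- solve_network(atree, bcs, record$blood, config)
  structure(list(vfpp_mmhg = extract_vfpp(sol, atree, config),
                 solution = sol, bcs = bcs, tree = atree, record = record,
                 config = config),
            class = "vfpp_fit")
}

#' @export
print.vfpp_fit <- function(x, ...) {
  cat(sprintf("vFPP fit for animal '%s' (%s)\n",
              x$record$animal_id %||% "<unnamed>",
              x$record$group %||% "?"))
  cat(sprintf("  vFPP = %.4f mmHg (p_ref %.3f mmHg + gauge %.4f mmHg)\n",
              x$vfpp_mmhg, x$config$p_ref, x$vfpp_mmhg - x$config$p_ref))
  if (!is.null(x$record$fpp_true_mmhg) && !is.na(x$record$fpp_true_mmhg))
    cat(sprintf("  invasive FPP = %.4f mmHg\n", x$record$fpp_true_mmhg))
  invisible(x)
}

#' @export
summary.vfpp_fit <- function(object, ...) {
  print(object)
  cat("\n"); print(object$solution)
  invisible(object)
}

#' @export
coef.vfpp_fit <- function(object, ...) {
  c(vfpp_mmhg = object$vfpp_mmhg,
    gauge_mmhg = object$vfpp_mmhg - object$config$p_ref,
    p_ref_mmhg = object$config$p_ref)
}

#' @export
plot.vfpp_fit <- function(x, ...) {
  # pressure along the flow path from each inlet to the reference node
  p <- pa_to_mmhg(x$solution$pressures_pa)
  graphics::barplot(sort(p, decreasing = TRUE),
                    ylab = "gauge pressure (mmHg)", las = 2,
                    main = sprintf("Nodal pressures, animal %s",
                                   x$record$animal_id %||% ""), ...)
  invisible(x)
}
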