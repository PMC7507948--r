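# Steady laminar network solver.
#
# Reduction of the incompressible Navier-Stokes equations to a resistive
# network: steady continuity at every junction (no mass sources) plus the
# fully developed laminar (Hagen-Poiseuille) momentum closure per segment.
# Gravity and external body forces are neglected (supine, venous scale);
# convective momentum and junction losses are outside the model.  The system
# is linear, so a single direct dense solve gives bit-reproducible pressures.

#' Solver configuration
#'
#' @param p_ref absolute reference pressure (mmHg) added to the gauge trunk
#'   pressure when extracting the virtual free portal pressure; default 0
#'   reports pure gauge values.
#' @param re_max Reynolds threshold above which a warning is issued (the
#'   laminar closure assumes Re well below transition; default 2000).
#' @param tol relative tolerance used by the residual checks.
#' @return a \code{solver_config} list.
#' @export
solver_config <- function(p_ref = 0, re_max = 2000, tol = 1e-10) {
  if (!is.numeric(tol) || tol <= 0)
    pf_stop("'tol' must be > 0", "pf_parameter_error")
  structure(list(p_ref = p_ref, re_max = re_max, tol = tol),
            class = "solver_config")
}

#' Hydraulic resistance of a linearly tapered segment
#'
#' Integrates the local Poiseuille resistance along a linear taper:
#' R = int_0^L 128 mu dx / (pi d(x)^4)
#'   = 128 mu L (d0^2 + d0 d1 + d1^2) / (3 pi d0^3 d1^3) in SI,
#' reducing to 128 mu L / (pi d^4) for a uniform tube.
#'
#' @param d_prox,d_dist proximal/distal inner diameters, mm.
#' @param length segment length, mm.
#' @param mu dynamic viscosity, Pa s.
#' @return resistance, Pa s / m^3.
#' @examples
#' segment_resistance(4.5, 4.5, 50, 3.5e-3)
#' @export
segment_resistance <- function(d_prox, d_dist, length, mu) {
  pf_check_positive(d_prox = d_prox, d_dist = d_dist, length = length, mu = mu)
  d0 <- d_prox / 1000; d1 <- d_dist / 1000; L <- length / 1000
  128 * mu * L * (d0^2 + d0 * d1 + d1^2) / (3 * pi * d0^3 * d1^3)
}

#' Poiseuille pressure drop in a uniform tube
#'
#' Analytic form dP = 128 mu L Q / (pi d^4); used as the closed-form oracle
#' for the network solver on single tubes.
#'
#' @param d inner diameter, mm.
#' @param length tube length, mm.
#' @param mu dynamic viscosity, Pa s.
#' @param Q volumetric flow, m^3/s (may be 0).
#' @return pressure drop, Pa.
#' @export
poiseuille_drop <- function(d, length, mu, Q) {
  pf_check_positive(d = d, length = length, mu = mu)
  if (!is.numeric(Q) || any(!is.finite(Q)))
    pf_stop("'Q' must be finite", "pf_parameter_error")
  128 * mu * (length / 1000) * Q / (pi * (d / 1000)^4)
}

#' Reynolds number at vessel scale
#'
#' Re = rho v d / mu in SI; a regime check for the laminar closure (canine
#' portal flow sits near Re ~ 300).
#'
#' @param d diameter, mm.
#' @param v velocity, cm/s.
#' @param rho density, kg/m^3.
#' @param mu viscosity, Pa s.
#' @return dimensionless Reynolds number.
#' @export
reynolds <- function(d, v, rho, mu) {
  pf_check_positive(d = d, v = v, rho = rho, mu = mu)
  rho * (v / 100) * (d / 1000) / mu
}

#' Solve steady laminar flow on a vessel network
#'
#' Assembles junction continuity with segment conductances 1/R and solves the
#' linear nodal system directly.  Velocity faces inject their signed flow at
#' their node; the unique reference face fixes the gauge pressure.
#'
#' @param tree a \code{vessel_tree}.
#' @param bcs a reconciled \code{bc_set} from \code{\link{assemble_bcs}} (or
#'   built manually and passed through \code{\link{reconcile_mass_balance}}).
#' @param blood list with \code{mu} (Pa s) and optionally \code{rho}
#'   (kg/m^3, used for the Reynolds check).
#' @param config a \code{\link{solver_config}}.
#' @return a \code{flow_solution}: nodal gauge pressures (Pa), segment flows
#'   (m^3/s, positive proximal -> distal), and residual diagnostics.
#' @export
solve_network <- function(tree, bcs, blood, config = solver_config()) {
  if (!isTRUE(attr(bcs, "reconciled")))
    pf_stop("boundary conditions must be mass-reconciled before solving",
            "pf_precondition_error")
  df <- as.data.frame(bcs)
  refs <- df[df$kind == "pressure_outlet", , drop = FALSE]
  if (nrow(refs) != 1L)
    pf_stop("exactly one pressure reference required", "pf_solver_error")
  mu <- blood$mu
  pf_check_positive(mu = mu)

  nodes <- tree$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  seg <- tree$segments
  R <- segment_resistance(seg$d_prox_mm, seg$d_dist_mm, seg$length_mm, mu)
  G <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(seg))) {
    a <- idx[[seg$node_prox[i]]]; b <- idx[[seg$node_dist[i]]]
    g <- 1 / R[i]
    G[a, a] <- G[a, a] + g; G[b, b] <- G[b, b] + g
    G[a, b] <- G[a, b] - g; G[b, a] <- G[b, a] - g
  }
  inj <- stats::setNames(numeric(n), nodes)
  vel <- df[df$kind == "velocity_inlet", , drop = FALSE]
  for (i in seq_len(nrow(vel))) {
    s <- if (vel$role[i] == "inlet") 1 else -1
    inj[vel$node[i]] <- inj[vel$node[i]] + s * vel$q_m3_s[i]
  }
  qscale <- max(abs(vel$q_m3_s), 0)
  # any net imbalance left after reconciliation discharges through the
  # pressure-outlet face; interior junction continuity is checked below
  ref_node <- refs$node[1]
  gauge <- refs$gauge_pa[1]
  unk <- setdiff(nodes, ref_node)
  p <- stats::setNames(numeric(n), nodes)
  p[ref_node] <- gauge
  if (length(unk)) {
    A <- G[unk, unk, drop = FALSE]
    rhs <- inj[unk] - G[unk, ref_node, drop = FALSE] %*% rep(gauge, 1)
    sol <- tryCatch(solve(A, rhs), error = function(e)
      pf_stop(sprintf("singular network system: %s", conditionMessage(e)),
              "pf_solver_error"))
    p[unk] <- as.numeric(sol)
  }

  qseg <- (p[seg$node_prox] - p[seg$node_dist]) / R
  names(qseg) <- seg$id

  # junction residuals at nodes without boundary injections
  net <- inj
  for (i in seq_len(nrow(seg))) {
    net[seg$node_prox[i]] <- net[seg$node_prox[i]] - qseg[i]
    net[seg$node_dist[i]] <- net[seg$node_dist[i]] + qseg[i]
  }
  interior <- setdiff(nodes, ref_node)
  resid <- if (length(interior) && qscale > 0)
    max(abs(net[interior])) / qscale else 0

  # Reynolds regime check on mean diameters
  if (!is.null(blood$rho)) {
    dm <- (seg$d_prox_mm + seg$d_dist_mm) / 2
    area <- (pi / 4) * (dm / 1000)^2
    vseg <- abs(qseg) / area                 # m/s
    re <- blood$rho * vseg * (dm / 1000) / mu
    if (any(re > config$re_max))
      warning(sprintf("Reynolds number exceeds %g in segment(s): %s",
                      config$re_max,
                      paste(seg$id[re > config$re_max], collapse = ", ")),
              call. = FALSE)
  }

  structure(list(pressures_pa = p, flows_m3_s = qseg,
                 residual_rel = resid, gauge_pa = gauge,
                 ref_node = ref_node, config = config),
            class = "flow_solution")
}

#' Extract the virtual free portal pressure
#'
#' The virtual free portal pressure is the pressure at the centre of the
#' portal-vein trunk: the trunk-midpoint gauge pressure (linear interpolation
#' between the trunk's end nodes) converted to mmHg, plus the configured
#' absolute reference \code{p_ref}.
#'
#' @param solution a \code{flow_solution}.
#' @param tree the solved \code{vessel_tree}.
#' @param config a \code{\link{solver_config}} (supplies \code{p_ref}).
#' @return virtual free portal pressure, mmHg.
#' @export
extract_vfpp <- function(solution, tree, config = solver_config()) {
  i <- which(tree$segments$name == "portal_vein")
  if (!length(i))
    pf_stop("tree has no portal_vein segment", "pf_config_error")
  s <- tree$segments[i[1], ]
  p_mid <- (solution$pressures_pa[[s$node_prox]] +
            solution$pressures_pa[[s$node_dist]]) / 2
  config$p_ref + pa_to_mmhg(p_mid)
}

#' Export a flow solution
#'
#' \code{write_flow_csv} writes nodal pressures (Pa and mmHg) and segment
#' flows; \code{write_flow_vtk} writes legacy-ASCII VTK polylines with
#' per-point pressure for visualisation.
#'
#' @param solution a \code{flow_solution}.
#' @param tree the solved tree.
#' @param path output path (CSV) or path prefix (VTK).
#' @export
write_flow_csv <- function(solution, tree, path) {
  nodes <- data.frame(record = "node", id = names(solution$pressures_pa),
                      p_pa = as.numeric(solution$pressures_pa),
                      p_mmhg = pa_to_mmhg(as.numeric(solution$pressures_pa)),
                      q_m3_s = NA_real_)
  segs <- data.frame(record = "segment", id = names(solution$flows_m3_s),
                     p_pa = NA_real_, p_mmhg = NA_real_,
                     q_m3_s = as.numeric(solution$flows_m3_s))
  utils::write.csv(rbind(nodes, segs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
write_flow_vtk <- function(solution, tree, path) {
  pos <- layout_tree(tree)
  nodes <- rownames(pos)
  idx <- stats::setNames(seq_along(nodes) - 1L, nodes)
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "portoflow pressure field",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", length(nodes))), con)
  writeLines(apply(pos, 1, function(p) paste(format(p, digits = 9),
                                             collapse = " ")), con)
  seg <- tree$segments
  writeLines(sprintf("LINES %d %d", nrow(seg), 3L * nrow(seg)), con)
  writeLines(paste(2L, idx[seg$node_prox], idx[seg$node_dist]), con)
  writeLines(c(sprintf("POINT_DATA %d", length(nodes)),
               "SCALARS pressure_Pa float 1", "LOOKUP_TABLE default"), con)
  writeLines(format(as.numeric(solution$pressures_pa[nodes]), digits = 9), con)
  invisible(path)
}

#' @export
print.flow_solution <- function(x, ...) {
  cat("Steady laminar network solution\n")
  cat(sprintf("  gauge reference: %g Pa at node '%s'\n", x$gauge_pa, x$ref_node))
  cat(sprintf("  nodal pressure range: %.4g .. %.4g Pa\n",
              min(x$pressures_pa), max(x$pressures_pa)))
  cat(sprintf("  max junction mass residual: %.3g (relative)\n", x$residual_rel))
  invisible(x)
}

#' @export
summary.flow_solution <- function(object, ...) {
  print(object)
  cat("\nNodal gauge pressures (Pa):\n")
  print(round(object$pressures_pa, 6))
  cat("\nSegment flows (m^3/s, proximal -> distal):\n")
  print(signif(object$flows_m3_s, 6))
  invisible(object)
}
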