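# Doppler measurements -> solver boundary conditions.
#
# Measurements arrive in clinical units (diameter mm, velocity cm/s); a
# boundary-condition set is always SI (m/s, m^3/s, Pa).  The conversion
# happens exactly once, inside assemble_bcs / flow_rate.

#' Mean velocity from a Doppler maximum
#'
#' Doppler traces of the portal system show a mean blood-flow velocity of
#' approximately 0.7 times the maximum; the factor is configurable because
#' it is an empirical approximation, not a constant of the physics.
#'
#' @param v_max maximum velocity, cm/s ( > 0 ).
#' @param factor mean/max ratio (default 0.7).
#' @return mean velocity, cm/s.
#' @examples
#' mean_velocity(33.8)  # 23.66
#' @export
mean_velocity <- function(v_max, factor = 0.7) {
  pf_check_positive(v_max = v_max, factor = factor)
  factor * v_max
}

#' Volumetric flow through a circular section
#'
#' Q = A v = (pi/4) d^2 v, with the clinical-unit inputs converted to SI.
#'
#' @param d inner diameter, mm.
#' @param v mean velocity, cm/s.
#' @return flow rate, m^3/s.
#' @examples
#' flow_rate(4.5, 23.66)  # 3.763e-06
#' @export
flow_rate <- function(d, v) {
  pf_check_positive(d = d, v = v)
  (pi / 4) * (d / 1000)^2 * (v / 100)
}

#' Rescale a measured velocity to a boundary face
#'
#' Conservation of Q between the ultrasound measurement site (diameter
#' \code{d_us}) and the model boundary face (diameter \code{d_b}) gives
#' v_b = (d_us^2 / d_b^2) v_us.
#'
#' @param d_us measured inner diameter, mm.
#' @param v_us measured (mean) velocity, cm/s.
#' @param d_b boundary-face diameter, mm.
#' @return boundary velocity, cm/s.
#' @export
boundary_velocity <- function(d_us, v_us, d_b) {
  pf_check_positive(d_us = d_us, v_us = v_us, d_b = d_b)
  (d_us^2 / d_b^2) * v_us
}

new_bc_set <- function(df, reconciled = FALSE, report = NULL) {
  structure(df, class = c("bc_set", "data.frame"),
            reconciled = reconciled, report = report)
}

#' Mass-balance reconciliation of velocity boundary conditions
#'
#' With measured velocities imposed on every inlet and outlet branch the
#' network is mass-over-determined.  Inflow measurements are kept as anchors
#' (splanchnic inflow drives the system) and all non-reference outlet flows
#' are rescaled by a common factor so that total inflow equals total outflow
#' exactly; the reference pressure-outlet face absorbs no flow.
#'
#' @param bcs a \code{bc_set} (see \code{\link{assemble_bcs}}) containing at
#'   least one velocity inlet and one velocity outlet.
#' @return the reconciled \code{bc_set}; attribute \code{report} holds the
#'   pre-reconciliation imbalance ratio and the applied factor.
#' @export
reconcile_mass_balance <- function(bcs) {
  df <- as.data.frame(bcs)
  vin <- df$kind == "velocity_inlet" & df$role == "inlet"
  vout <- df$kind == "velocity_inlet" & df$role == "outlet"
  if (!any(vin) || !any(vout))
    pf_stop("need >= 1 velocity inlet and >= 1 non-reference velocity outlet",
            "pf_parameter_error")
  q_in <- sum(df$q_m3_s[vin])
  q_out <- sum(df$q_m3_s[vout])
  if (q_out <= 0 && q_in > 0)
    pf_stop("zero total outflow with nonzero inflow: cannot reconcile",
            "pf_reconciliation_error")
  imbalance <- (q_in - q_out) / max(q_in, q_out)
  factor <- if (abs(imbalance) < 1e-12) 1 else q_in / q_out
  df$q_m3_s[vout] <- df$q_m3_s[vout] * factor
  df$v_b_m_s[vout] <- df$v_b_m_s[vout] * factor
  new_bc_set(df, reconciled = TRUE,
             report = list(imbalance_ratio = imbalance, factor = factor))
}

#' Assemble boundary conditions for one animal
#'
#' Maps an animal's Doppler set onto the tree's boundary faces: the
#' reference face becomes a gauge-0 pressure outlet; splenic / superior
#' mesenteric / inferior mesenteric faces become velocity inlets; left and
#' right portal faces become velocity outlets.  Every velocity passes
#' through \code{\link{mean_velocity}} and \code{\link{boundary_velocity}},
#' and \code{\link{reconcile_mass_balance}} is applied last.  A measurement
#' flagged hepatofugal (direction reversed) has its sign flipped with a
#' warning.
#'
#' @param record an animal record (see \code{\link{get_animal}}); needs one
#'   measurement per boundary vessel.
#' @param tree a \code{vessel_tree}.
#' @param mean_factor mean/max velocity ratio (default 0.7).
#' @return a reconciled \code{bc_set}: one row per face with columns
#'   \code{face}, \code{node}, \code{role}, \code{kind}, \code{d_b_mm},
#'   \code{v_b_m_s}, \code{q_m3_s}, \code{gauge_pa}.
#' @export
assemble_bcs <- function(record, tree, mean_factor = 0.7) {
  faces <- tree$faces
  meas <- record$vessels
  rows <- vector("list", nrow(faces))
  for (i in seq_len(nrow(faces))) {
    f <- faces[i, ]
    if (f$role == "reference_outlet") {
      rows[[i]] <- data.frame(face = f$id, node = f$node, role = f$role,
                              kind = "pressure_outlet", d_b_mm = f$diameter_mm,
                              v_b_m_s = NA_real_, q_m3_s = NA_real_,
                              gauge_pa = 0, stringsAsFactors = FALSE)
      next
    }
    seg <- face_segment(tree, f$node)
    m <- meas[meas$vessel == seg$name, , drop = FALSE]
    if (nrow(m) != 1L)
      pf_stop(sprintf("missing Doppler measurement for vessel '%s' (face '%s')",
                      seg$name, f$id), "pf_config_error")
    v_mean <- mean_velocity(m$vmax_cm_s, factor = mean_factor)
    v_b <- boundary_velocity(m$d_us_mm, v_mean, f$diameter_mm)
    q <- flow_rate(f$diameter_mm, v_b)
    dir <- m$direction %||% "toward_liver"
    if (!is.null(m$direction) && length(m$direction) &&
        identical(m$direction, "away_from_liver") && f$role == "inlet") {
      warning(sprintf("hepatofugal flow in vessel '%s'; flow sign reversed",
                      seg$name), call. = FALSE)
      q <- -q; v_b <- -v_b
    }
    rows[[i]] <- data.frame(face = f$id, node = f$node, role = f$role,
                            kind = "velocity_inlet", d_b_mm = f$diameter_mm,
                            v_b_m_s = v_b / 100, q_m3_s = q,
                            gauge_pa = NA_real_, stringsAsFactors = FALSE)
  }
  reconcile_mass_balance(new_bc_set(do.call(rbind, rows)))
}

#' Serialise a boundary-condition set to JSON
#' @param bcs a \code{bc_set}.
#' @param path output path.
#' @export
write_bcs <- function(bcs, path) {
  df <- as.data.frame(bcs)
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    x <- list(face = r$face, kind = r$kind)
    if (r$kind == "pressure_outlet") x$gauge_Pa <- r$gauge_pa
    else { x$v_b_m_s <- r$v_b_m_s; x$Q_m3_s <- r$q_m3_s }
    x
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.bc_set <- function(x, ...) {
  cat(sprintf("Boundary conditions (%d faces, %s)\n", nrow(x),
              if (isTRUE(attr(x, "reconciled"))) "mass-balanced" else "raw"))
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  rep <- attr(x, "report")
  if (!is.null(rep))
    cat(sprintf("imbalance ratio %.3g, outflow factor %.6g\n",
                rep$imbalance_ratio, rep$factor))
  invisible(x)
}
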