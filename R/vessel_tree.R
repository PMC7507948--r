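# Portal venous tree: data model and validation.
#
# A tree is a set of vessel segments (straight tubes with linear taper)
# joined at shared nodes, plus boundary faces where flow enters or leaves.
# Velocity-carrying faces (roles "inlet"/"outlet") must sit on free (degree-1)
# nodes; the single "reference_outlet" face pins the gauge pressure and may
# sit on any node, because after mass reconciliation it carries no net flow.

.VESSEL_NAMES <- c("portal_vein", "left_portal", "right_portal",
                   "splenic", "superior_mesenteric", "inferior_mesenteric",
                   "other")

#' Build a portal vessel tree
#'
#' Constructs and validates a \code{vessel_tree}: the topology and geometry
#' of a portal venous system (portal-vein trunk plus left/right portal,
#' splenic, superior and inferior mesenteric branches, or any other
#' configuration of tapered tubes joined at nodes).
#'
#' @param segments data frame with columns \code{id}, \code{name} (one of
#'   portal_vein, left_portal, right_portal, splenic, superior_mesenteric,
#'   inferior_mesenteric, other), \code{length_mm}, \code{d_prox_mm},
#'   \code{d_dist_mm}, \code{node_prox}, \code{node_dist}.
#' @param faces data frame with columns \code{id}, \code{node},
#'   \code{diameter_mm}, \code{role} (inlet, outlet or reference_outlet).
#' @param nodes optional character vector of node ids; defaults to the nodes
#'   referenced by \code{segments}.  Extra declared nodes are flagged as
#'   isolated by \code{\link{validate_tree}}.
#' @return an object of class \code{vessel_tree}.
#' @seealso \code{\link{canonical_tree}}, \code{\link{validate_tree}},
#'   \code{\link{read_tree}}
#' @examples
#' seg <- data.frame(id = "s1", name = "portal_vein", length_mm = 20,
#'                   d_prox_mm = 4, d_dist_mm = 4,
#'                   node_prox = "a", node_dist = "b")
#' fac <- data.frame(id = c("in", "out"), node = c("a", "b"),
#'                   diameter_mm = 4, role = c("inlet", "reference_outlet"))
#' tr <- vessel_tree(seg, fac)
#' @export
vessel_tree <- function(segments, faces, nodes = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  faces <- as.data.frame(faces, stringsAsFactors = FALSE)
  need_s <- c("id", "name", "length_mm", "d_prox_mm", "d_dist_mm",
              "node_prox", "node_dist")
  if (!all(need_s %in% names(segments)) || nrow(segments) < 1L)
    pf_stop("'segments' must have >= 1 row with columns id, name, length_mm, d_prox_mm, d_dist_mm, node_prox, node_dist",
            "pf_config_error")
  need_f <- c("id", "node", "diameter_mm", "role")
  if (!all(need_f %in% names(faces)))
    pf_stop("'faces' must have columns id, node, diameter_mm, role",
            "pf_config_error")
  if (is.null(nodes))
    nodes <- unique(c(segments$node_prox, segments$node_dist))
  tree <- structure(list(segments = segments, faces = faces,
                         nodes = as.character(nodes)),
                    class = "vessel_tree")

  viol <- validate_tree(tree)
  if (length(viol)) {
    cls <- "pf_validation_error"
    if (any(grepl("reference_outlet", viol))) cls <- "pf_config_error"
    if (any(grepl("disconnect|isolated", viol))) cls <- "pf_topology_error"
    pf_stop(paste0("invalid vessel tree:\n  - ",
                   paste(viol, collapse = "\n  - ")), cls)
  }
  tree
}

#' Build a tree from a structured specification
#'
#' Accepts the JSON-style nested description used in configuration files
#' (\code{segments} with \code{nodes = [a, b]} pairs, \code{faces}).
#'
#' @param tree_spec a list with elements \code{segments} and \code{faces}, as
#'   produced by parsing the tree JSON config.
#' @return a \code{vessel_tree}.
#' @export
build_tree <- function(tree_spec) {
  if (is.null(tree_spec$segments) || length(tree_spec$segments) == 0L)
    pf_stop("tree spec lists no segments", "pf_config_error")
  segs <- tree_spec$segments
  if (is.data.frame(segs)) {
    if (!is.null(segs$nodes)) {
      nd <- do.call(rbind, segs$nodes)
      segs$node_prox <- nd[, 1]; segs$node_dist <- nd[, 2]
      segs$nodes <- NULL
    }
  } else {
    segs <- do.call(rbind, lapply(segs, function(s) {
      data.frame(id = s$id, name = s$name, length_mm = s$length_mm,
                 d_prox_mm = s$d_prox_mm, d_dist_mm = s$d_dist_mm,
                 node_prox = s$nodes[[1]], node_dist = s$nodes[[2]],
                 stringsAsFactors = FALSE)
    }))
  }
  faces <- tree_spec$faces
  if (!is.data.frame(faces))
    faces <- do.call(rbind, lapply(faces, function(f)
      data.frame(id = f$id, node = f$node, diameter_mm = f$diameter_mm,
                 role = f$role, stringsAsFactors = FALSE)))
  vessel_tree(segs, faces, nodes = tree_spec$nodes)
}

#' Validate a vessel tree
#'
#' Reports every violated structural invariant; an empty character vector
#' means the tree is valid.  Unlike \code{\link{vessel_tree}}, this never
#' throws.
#'
#' @param tree a \code{vessel_tree} (or a bare list with the same fields).
#' @return character vector of violation descriptions, each naming the
#'   offending element.
#' @export
validate_tree <- function(tree) {
  v <- character(0)
  seg <- tree$segments; faces <- tree$faces; nodes <- tree$nodes

  for (i in seq_len(nrow(seg))) {
    s <- seg[i, ]
    for (fld in c("length_mm", "d_prox_mm", "d_dist_mm"))
      if (!is.finite(s[[fld]]) || s[[fld]] <= 0)
        v <- c(v, sprintf("segment '%s': %s must be > 0", s$id, fld))
    if (identical(s$node_prox, s$node_dist))
      v <- c(v, sprintf("segment '%s': node_prox equals node_dist", s$id))
    if (!(s$name %in% .VESSEL_NAMES))
      v <- c(v, sprintf("segment '%s': unknown vessel name '%s'", s$id, s$name))
  }
  if (anyDuplicated(seg$id))
    v <- c(v, "duplicate segment ids")

  deg <- table(factor(c(seg$node_prox, seg$node_dist), levels = nodes))
  iso <- names(deg)[deg == 0]
  if (length(iso))
    v <- c(v, sprintf("node '%s': isolated (degree 0)", iso))

  # connectivity over nodes that belong to segments
  used <- unique(c(seg$node_prox, seg$node_dist))
  if (length(used) > 1L) {
    adj <- split(c(seg$node_dist, seg$node_prox),
                 c(seg$node_prox, seg$node_dist))
    seen <- used[1]; frontier <- used[1]
    while (length(frontier)) {
      nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(setdiff(used, seen)))
      v <- c(v, sprintf("graph is disconnected (unreachable nodes: %s)",
                        paste(setdiff(used, seen), collapse = ", ")))
  }

  if (nrow(faces)) {
    bad_node <- !(faces$node %in% nodes)
    if (any(bad_node))
      v <- c(v, sprintf("face '%s': unknown node '%s'",
                        faces$id[bad_node], faces$node[bad_node]))
    if (any(!faces$role %in% c("inlet", "outlet", "reference_outlet")))
      v <- c(v, "face roles must be inlet, outlet or reference_outlet")
    if (any(!is.finite(faces$diameter_mm) | faces$diameter_mm <= 0))
      v <- c(v, sprintf("face '%s': diameter must be > 0",
                        faces$id[!is.finite(faces$diameter_mm) | faces$diameter_mm <= 0]))
    # velocity faces sit on free ends
    vel <- faces[faces$role %in% c("inlet", "outlet") & faces$node %in% nodes, , drop = FALSE]
    if (nrow(vel)) {
      d1 <- deg[vel$node] == 1
      if (any(!d1, na.rm = TRUE))
        v <- c(v, sprintf("face '%s': inlet/outlet face must sit on a degree-1 node",
                          vel$id[!d1]))
    }
  }
  nref <- sum(faces$role == "reference_outlet")
  if (nref != 1L)
    v <- c(v, sprintf("exactly one reference_outlet face required (found %d)", nref))

  # interior (face-free) nodes must not dead-end
  interior <- setdiff(nodes, faces$node)
  bad_int <- interior[deg[interior] == 1]
  if (length(bad_int))
    v <- c(v, sprintf("node '%s': non-boundary node has degree 1", bad_int))

  v
}

# Table of per-vessel diameters (mm) of the healthy (control) template.
.CANONICAL_D <- c(portal_vein = 4.5, left_portal = 3.4, right_portal = 4.2,
                  splenic = 1.8, superior_mesenteric = 3.1,
                  inferior_mesenteric = 2.0)
# Segment lengths (mm): not reported by imaging tables; package defaults at
# canine scale.
.CANONICAL_L <- c(portal_vein = 45, left_portal = 25, right_portal = 25,
                  splenic = 40, superior_mesenteric = 50,
                  inferior_mesenteric = 45)

#' Canonical canine portal-tree template
#'
#' Six named vessels: splenic, superior and inferior mesenteric veins joining
#' at the portosplenic confluence, the portal-vein trunk running from the
#' confluence to the liver hilum, and the left/right portal branches leaving
#' the hilum.  Velocity faces sit at the five free branch ends; the gauge
#' reference face sits on the trunk at the hilum (it carries no net flow once
#' boundary flows are mass-balanced).
#'
#' @param diameters named numeric vector of per-vessel diameters (mm);
#'   defaults to the healthy-control values.
#' @param lengths named numeric vector of per-vessel lengths (mm).
#' @return a \code{vessel_tree} with 6 segments, 7 nodes and 6 boundary faces.
#' @examples
#' tr <- canonical_tree()
#' validate_tree(tr)  # character(0)
#' @export
canonical_tree <- function(diameters = .CANONICAL_D, lengths = .CANONICAL_L) {
  d <- .CANONICAL_D; d[names(diameters)] <- diameters
  L <- .CANONICAL_L; L[names(lengths)] <- lengths
  segs <- data.frame(
    id = c("seg_sv", "seg_smv", "seg_imv", "seg_pv", "seg_lpv", "seg_rpv"),
    name = c("splenic", "superior_mesenteric", "inferior_mesenteric",
             "portal_vein", "left_portal", "right_portal"),
    length_mm = unname(L[c("splenic", "superior_mesenteric",
                           "inferior_mesenteric", "portal_vein",
                           "left_portal", "right_portal")]),
    d_prox_mm = unname(d[c("splenic", "superior_mesenteric",
                           "inferior_mesenteric", "portal_vein",
                           "left_portal", "right_portal")]),
    d_dist_mm = unname(d[c("splenic", "superior_mesenteric",
                           "inferior_mesenteric", "portal_vein",
                           "left_portal", "right_portal")]),
    node_prox = c("sv_end", "smv_end", "imv_end", "confluence",
                  "hilum", "hilum"),
    node_dist = c("confluence", "confluence", "confluence", "hilum",
                  "lpv_end", "rpv_end"),
    stringsAsFactors = FALSE)
  faces <- data.frame(
    id = c("f_sv", "f_smv", "f_imv", "f_lpv", "f_rpv", "f_pv"),
    node = c("sv_end", "smv_end", "imv_end", "lpv_end", "rpv_end", "hilum"),
    diameter_mm = unname(d[c("splenic", "superior_mesenteric",
                             "inferior_mesenteric", "left_portal",
                             "right_portal", "portal_vein")]),
    role = c("inlet", "inlet", "inlet", "outlet", "outlet",
             "reference_outlet"),
    stringsAsFactors = FALSE)
  vessel_tree(segs, faces)
}

#' Read / write a tree JSON configuration
#'
#' The on-disk format is
#' \code{{"segments": [{"id", "name", "length_mm", "d_prox_mm", "d_dist_mm",
#' "nodes": [a, b]}], "faces": [{"id", "node", "diameter_mm", "role"}]}}.
#'
#' @param path file path.
#' @return \code{read_tree}: a \code{vessel_tree}.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) pf_stop(sprintf("no such file: %s", path), "pf_io_error")
  build_tree(jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                                simplifyVector = TRUE))
}

#' @rdname read_tree
#' @param tree a \code{vessel_tree}.
#' @export
write_tree <- function(tree, path) {
  seg <- tree$segments
  spec <- list(
    segments = lapply(seq_len(nrow(seg)), function(i)
      list(id = seg$id[i], name = seg$name[i], length_mm = seg$length_mm[i],
           d_prox_mm = seg$d_prox_mm[i], d_dist_mm = seg$d_dist_mm[i],
           nodes = c(seg$node_prox[i], seg$node_dist[i]))),
    faces = lapply(seq_len(nrow(tree$faces)), function(i)
      as.list(tree$faces[i, ])))
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# degree of each node
tree_degree <- function(tree) {
  table(factor(c(tree$segments$node_prox, tree$segments$node_dist),
               levels = tree$nodes))
}

# segment attached to a (degree-1) face node
face_segment <- function(tree, node) {
  i <- which(tree$segments$node_prox == node | tree$segments$node_dist == node)
  tree$segments[i[1], , drop = FALSE]
}

#' @export
print.vessel_tree <- function(x, ...) {
  cat(sprintf("Portal vessel tree: %d segments, %d nodes, %d boundary faces\n",
              nrow(x$segments), length(x$nodes), nrow(x$faces)))
  cat(sprintf("  vessels: %s\n", paste(x$segments$name, collapse = ", ")))
  ref <- x$faces[x$faces$role == "reference_outlet", ]
  cat(sprintf("  gauge reference at node '%s' (face '%s')\n", ref$node, ref$id))
  invisible(x)
}

#' @export
summary.vessel_tree <- function(object, ...) {
  print(object)
  seg <- object$segments
  cat("\nSegments (mm):\n")
  print(data.frame(vessel = seg$name, length = seg$length_mm,
                   d_prox = seg$d_prox_mm, d_dist = seg$d_dist_mm),
        row.names = FALSE)
  invisible(object)
}
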