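# Shared fixtures: minimal trees, random networks, hand-built BC sets.

single_tube_tree <- function(d_prox = 4, d_dist = d_prox, L = 20,
                             name = "portal_vein") {
  vessel_tree(
    data.frame(id = "s1", name = name, length_mm = L,
               d_prox_mm = d_prox, d_dist_mm = d_dist,
               node_prox = "a", node_dist = "b", stringsAsFactors = FALSE),
    data.frame(id = c("f_in", "f_out"), node = c("a", "b"),
               diameter_mm = c(d_prox, d_dist),
               role = c("inlet", "reference_outlet"),
               stringsAsFactors = FALSE))
}

# a symmetric Y: two identical inlets joining into one outlet limb
y_tree <- function(d = 4, L = 20) {
  vessel_tree(
    data.frame(id = c("sL", "sR", "sOut"),
               name = c("other", "other", "portal_vein"),
               length_mm = L, d_prox_mm = d, d_dist_mm = d,
               node_prox = c("inL", "inR", "j"),
               node_dist = c("j", "j", "out"), stringsAsFactors = FALSE),
    data.frame(id = c("fL", "fR", "fOut"),
               node = c("inL", "inR", "out"), diameter_mm = d,
               role = c("inlet", "inlet", "reference_outlet"),
               stringsAsFactors = FALSE))
}

# a BC set imposing flow Q at every inlet node and the gauge at the
# reference face; outlets (if any) get given signed magnitudes then
# reconciliation.  q_in / q_out are named by face id.
make_bcs <- function(tree, q_in, q_out = NULL, reconcile = TRUE) {
  faces <- tree$faces
  rows <- lapply(seq_len(nrow(faces)), function(i) {
    f <- faces[i, ]
    if (f$role == "reference_outlet")
      return(data.frame(face = f$id, node = f$node, role = f$role,
                        kind = "pressure_outlet", d_b_mm = f$diameter_mm,
                        v_b_m_s = NA_real_, q_m3_s = NA_real_, gauge_pa = 0,
                        stringsAsFactors = FALSE))
    q <- if (f$role == "inlet") q_in[[f$id]] else q_out[[f$id]]
    a <- (pi / 4) * (f$diameter_mm / 1000)^2
    data.frame(face = f$id, node = f$node, role = f$role,
               kind = "velocity_inlet", d_b_mm = f$diameter_mm,
               v_b_m_s = q / a, q_m3_s = q, gauge_pa = NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (reconcile && any(df$role == "outlet")) return(reconcile_mass_balance(df))
  structure(df, class = c("bc_set", "data.frame"), reconciled = TRUE)
}

# random tree with <= max_seg segments and >= 3 leaves; returns the tree
# plus a reconciled BC set with random flows
random_network <- function(seed, max_seg = 50) {
  set.seed(seed)
  repeat {
    k <- sample(3:max_seg, 1)
    node_of <- function(i) sprintf("n%d", i)
    parent <- c(NA, vapply(2:(k + 1), function(i) sample(i - 1, 1), 0L))
    segs <- data.frame(
      id = sprintf("e%d", 2:(k + 1)),
      name = "other",
      length_mm = runif(k, 5, 60),
      d_prox_mm = runif(k, 1.5, 9),
      d_dist_mm = runif(k, 1.5, 9),
      node_prox = node_of(parent[2:(k + 1)]),
      node_dist = node_of(2:(k + 1)), stringsAsFactors = FALSE)
    deg <- table(c(segs$node_prox, segs$node_dist))
    leaves <- names(deg)[deg == 1]
    if (length(leaves) >= 3) break
  }
  roles <- c("reference_outlet",
             sample(c("inlet", "outlet",
                      sample(c("inlet", "outlet"), length(leaves) - 3,
                             replace = TRUE))))
  faces <- data.frame(id = paste0("f_", leaves), node = leaves,
                      diameter_mm = runif(length(leaves), 1.5, 9),
                      role = roles, stringsAsFactors = FALSE)
  tree <- vessel_tree(segs, faces)
  q_in <- stats::setNames(runif(sum(roles == "inlet"), 1e-7, 5e-6),
                          faces$id[roles == "inlet"])
  q_out <- stats::setNames(runif(sum(roles == "outlet"), 1e-7, 5e-6),
                           faces$id[roles == "outlet"])
  list(tree = tree, bcs = make_bcs(tree, q_in, q_out))
}

canine_blood <- function(mu = 3.5e-3, rho = 1050) list(mu = mu, rho = rho)

# brute-force AUC over all positive-negative pairs
auc_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}
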