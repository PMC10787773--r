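# Shared tiny fixtures, built in code.

# single straight pipe: inlet -> out, one outlet at the far end
pipe_network <- function(radius = 1e-3, length = 0.1, dz = 0,
                         r_out = 1e9) {
  nodes <- data.frame(node = c("in", "out"), z = c(0, dz))
  segs <- data.frame(segment_id = "pipe", from = "in", to = "out",
                     radius_m = radius, length_m = max(length, abs(dz)),
                     delta_z_m = dz, region = "test",
                     stringsAsFactors = FALSE)
  outs <- make_outlet_spec("o1", "test", radius, r_out)
  outs$node <- "out"
  vessel_network(nodes, segs, "in", outs)
}

# symmetric Y: inlet trunk splitting into two identical branches
y_network <- function(r_out = 1e9) {
  nodes <- data.frame(node = c("in", "j", "a", "b"), z = 0)
  segs <- data.frame(
    segment_id = c("trunk", "br_a", "br_b"),
    from = c("in", "j", "j"), to = c("j", "a", "b"),
    radius_m = c(2e-3, 1e-3, 1e-3), length_m = c(0.05, 0.04, 0.04),
    delta_z_m = 0, region = "test", stringsAsFactors = FALSE)
  outs <- rbind(make_outlet_spec("oa", "test", 1e-3, r_out),
                make_outlet_spec("ob", "test", 1e-3, r_out))
  outs$node <- c("a", "b")
  vessel_network(nodes, segs, "in", outs)
}

# star network: every outlet attached directly at the single hub node
# (no conduit segments), so region flow fractions are exactly those of
# the designed outlet resistances.
star_network <- function(outlet_table) {
  nodes <- data.frame(node = "hub", z = 0)
  segs <- data.frame(segment_id = character(0), from = character(0),
                     to = character(0), radius_m = numeric(0),
                     length_m = numeric(0), delta_z_m = numeric(0),
                     region = character(0), stringsAsFactors = FALSE)
  out <- outlet_table
  out$node <- "hub"
  vessel_network(nodes, segs, "hub", out)
}

# flatten a tree_segment into a segment table with integer node ids
# (0 = root's upstream node)
flatten_tree <- function(tree) {
  env <- new.env()
  env$rows <- list()
  env$next_id <- 1L
  walk <- function(node, parent) {
    id <- env$next_id
    env$next_id <- id + 1L
    env$rows[[id]] <- data.frame(
      from = parent, to = id, radius = node$radius, length = node$length,
      leaf = length(node$children) == 0)
    if (length(node$children) == 2) {
      walk(node$children[[1]], id)
      walk(node$children[[2]], id)
    }
  }
  walk(tree, 0L)
  do.call(rbind, env$rows)
}

# independent nodal-solve oracle for a structured tree's resistance:
# assemble the flattened tree as a resistor network, unit pressure at
# the upstream node, leaves' distal ends grounded, R = 1/inflow.
# Independent of tree_resistance's series/parallel recursion.
tree_resistance_oracle <- function(tree, params) {
  seg <- flatten_tree(tree)
  mu <- fl_effective_viscosity(2 * seg$radius, params)
  seg$R <- 8 * mu * seg$length / (pi * seg$radius^4)
  # unknowns: pressures at every 'to' node that is not a leaf's distal
  # datum -- i.e. all internal junctions.  Leaf segments drain from their
  # 'from' junction to ground through R; model leaf 'to' nodes as ground.
  interior <- seg$to[!seg$leaf]
  idx <- stats::setNames(seq_along(interior), interior)
  n <- length(interior)
  if (n == 0) return(seg$R[1])  # single-segment tree
  G <- matrix(0, n, n)
  b <- numeric(n)
  for (k in seq_len(nrow(seg))) {
    g <- 1 / seg$R[k]
    fi <- idx[as.character(seg$from[k])]
    ti <- if (seg$leaf[k]) NA_integer_ else idx[as.character(seg$to[k])]
    if (!is.na(fi)) G[fi, fi] <- G[fi, fi] + g
    if (!is.na(ti)) G[ti, ti] <- G[ti, ti] + g
    if (!is.na(fi) && !is.na(ti)) {
      G[fi, ti] <- G[fi, ti] - g
      G[ti, fi] <- G[ti, fi] - g
    }
    if (is.na(fi) && !is.na(ti)) b[ti] <- b[ti] + g * 1  # from root, P=1
  }
  p <- solve(G, b)
  root_k <- which(seg$from == 0L)
  p_below <- p[idx[as.character(seg$to[root_k])]]
  1 / ((1 - p_below) / seg$R[root_k])
}

# brute-force plain recursion oracle for leaf count / depth of the
# exponent-law tree (independent re-derivation of the stopping rule)
tree_shape_oracle <- function(root_radius, k, alpha, dterm) {
  s1 <- (1 + alpha^k)^(-1 / k)
  s2 <- alpha * s1
  rec <- function(r, depth) {
    r1 <- r * s1; r2 <- r * s2
    if (2 * r1 < dterm || 2 * r2 < dterm) {
      return(c(1, depth))
    }
    a <- rec(r1, depth + 1)
    b <- rec(r2, depth + 1)
    c(a[1] + b[1], max(a[2], b[2]))
  }
  rec(root_radius, 1)
}

default_params <- rheology_params()
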