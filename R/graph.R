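# Molecular graph tables derived from ChemmineR SDF objects.
#
# A graph is a plain list with parallel vectors:
#   sym, z, charge, nh, inring  (per atom)
#   bfrom, bto, border          (per bond, 1-based indices, kekulized orders)
#   coords                      (n x 3 matrix, present when the SDF carries 3D)
# Hydrogens are implicit: nh is reconstructed from standard valences, so all
# downstream code (fingerprints, descriptors, feature selections) operates on
# the heavy-atom skeleton.

.element_z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14, P = 15,
                S = 16, Cl = 17, Br = 35, I = 53)

# default valences used to infer implicit hydrogen counts on kekulized graphs
.implicit_h <- function(z, charge, bond_order_sum) {
  val <- rep(0L, length(z))
  val[z == 5] <- 3L
  val[z == 6] <- 4L
  val[z == 7] <- 3L
  val[z == 8] <- 2L
  val[z %in% c(9, 17, 35, 53)] <- 1L
  val[z == 14] <- 4L
  # P and S take the smallest standard valence that accommodates the bonds
  for (i in which(z == 15)) val[i] <- if (bond_order_sum[i] > 3) 5L else 3L
  for (i in which(z == 16)) {
    val[i] <- if (bond_order_sum[i] > 4) 6L else if (bond_order_sum[i] > 2) 4L else 2L
  }
  # charge shifts the effective valence (e.g. O- -> 1, N+ -> 4)
  eff <- val + ifelse(z %in% c(7, 15), charge, 0L) -
    ifelse(z %in% c(8, 16), abs(charge), 0L) - ifelse(z == 6, abs(charge), 0L)
  pmax(0L, eff - bond_order_sum)
}

.charge_from_code <- function(code) {
  out <- integer(length(code))
  out[code >= 1 & code <= 3] <- 4L - code[code >= 1 & code <= 3]
  out[code >= 5 & code <= 7] <- -(code[code >= 5 & code <= 7] - 4L)
  out
}

#' Build a molecular graph from a ChemmineR SDF record
#'
#' @param sdf a `ChemmineR::SDF` object (one molecule)
#' @return a graph list (atoms, bonds, implicit hydrogens, ring flags, and
#'   coordinates when present)
#' @keywords internal
mol_graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- gsub("_.*$", "", rownames(ab))
  z <- unname(.element_z[sym])
  if (anyNA(z)) {
    stop("unsupported element(s): ", paste(unique(sym[is.na(z)]), collapse = ", "))
  }
  charge <- if ("C6" %in% colnames(ab)) .charge_from_code(as.integer(ab[, "C6"])) else integer(length(z))
  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) %/% 7, byrow = FALSE)
  nb <- nrow(bb)
  bfrom <- as.integer(bb[, 1]); bto <- as.integer(bb[, 2]); border <- as.integer(bb[, 3])
  bos <- integer(length(z))
  for (k in seq_len(nb)) {
    bos[bfrom[k]] <- bos[bfrom[k]] + border[k]
    bos[bto[k]] <- bos[bto[k]] + border[k]
  }
  # drop explicit hydrogens if any (fold into neighbour nh)
  keep <- z != 1L
  nh_explicit <- integer(length(z))
  if (!all(keep)) {
    hidx <- which(!keep)
    for (k in seq_len(nb)) {
      if (bfrom[k] %in% hidx) nh_explicit[bto[k]] <- nh_explicit[bto[k]] + 1L
      if (bto[k] %in% hidx) nh_explicit[bfrom[k]] <- nh_explicit[bfrom[k]] + 1L
    }
    remap <- cumsum(keep)
    bkeep <- keep[bfrom] & keep[bto]
    bfrom <- remap[bfrom[bkeep]]; bto <- remap[bto[bkeep]]; border <- border[bkeep]
    sym <- sym[keep]; z <- z[keep]; charge <- charge[keep]
    # bond-order sums keep the explicit-H contributions so the implicit-H
    # formula yields only the hydrogens not drawn explicitly
    bos <- bos[keep]
    nh_explicit <- nh_explicit[keep]
  }
  nh <- .implicit_h(z, charge, bos) + nh_explicit
  g <- list(sym = sym, z = z, charge = charge, nh = nh,
            inring = integer(length(z)),
            bfrom = bfrom, bto = bto, border = border)
  ri <- cpp_ring_info(g$z, g$charge, g$nh, g$inring, g$bfrom, g$bto, g$border)
  g$inring <- as.integer(ri$atom_ring)
  g$bond_ring <- ri$bond_ring
  # perceive aromatic rings on the kekulized graph, then normalize their bond
  # orders so downstream hashing is independent of the emitted kekule form
  g$arom_rings <- .aromatic_rings(g)
  g$arom_atoms <- sort(unique(unlist(g$arom_rings)))
  for (r in g$arom_rings) {
    sel <- g$bond_ring & g$bfrom %in% r & g$bto %in% r
    g$border[sel] <- 4L
  }
  coords <- ab[, 1:3, drop = FALSE]
  if (any(coords[, 3] != 0) || all(coords[, 1:2] == 0)) g$coords <- unname(coords)
  g$coords2d <- unname(coords)
  g
}

#' Parse SMILES into molecular graphs
#'
#' Structures are parsed with OpenBabel (via ChemmineOB); unparseable entries
#' are reported, not silently dropped.
#'
#' @param smiles character vector of SMILES, optionally named by id
#' @return list with `graphs` (named list) and `failures` (character vector of
#'   ids that failed to parse)
#' @keywords internal
mol_graphs_from_smiles <- function(smiles) {
  ids <- names(smiles)
  if (is.null(ids)) ids <- paste0("M", seq_along(smiles))
  graphs <- vector("list", length(smiles))
  names(graphs) <- ids
  failures <- character(0)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids))),
                     error = function(e) NULL)
  ok_ids <- if (is.null(sdfset)) character(0) else ChemmineR::sdfid(sdfset)
  for (i in seq_along(smiles)) {
    id <- ids[[i]]
    sdf <- NULL
    if (id %in% ok_ids) {
      sdf <- sdfset[[match(id, ok_ids)]]
      if (length(ChemmineR::atomblock(sdf)) == 0) sdf <- NULL
    } else {
      sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[i], id))[[1]]),
                      error = function(e) NULL)
    }
    g <- if (!is.null(sdf)) tryCatch(mol_graph_from_sdf(sdf), error = function(e) NULL)
    if (is.null(g)) failures <- c(failures, id) else graphs[[id]] <- g
  }
  list(graphs = graphs[!vapply(graphs, is.null, logical(1))], failures = failures)
}

# number of smallest rings (cyclomatic number: bonds - atoms + components)
.n_rings_graph <- function(g) {
  n <- length(g$z)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(g$bfrom)) {
    a <- find(g$bfrom[k]); b <- find(g$bto[k])
    if (a != b) parent[a] <- b
  }
  comps <- length(unique(vapply(seq_len(n), find, integer(1))))
  as.integer(length(g$bfrom) - n + comps)
}

# ---- per-atom feature predicates -------------------------------------------
# Rule-based equivalents of the conventional SMARTS definitions, evaluated on
# the heavy-atom graph (documented in the package vignette):
#   carboxylic_acid  [CX3](=O)[OX2H1,OX1-]  -> the carboxyl carbon
#   sulphone         S(=O)(=O)              -> the sulphur
#   sulfonamide      S(=O)(=O)N             -> the sulphur
#   amide            C(=O)N                 -> the carbonyl carbon
#   hbd              [N,O;!H0]              -> N/O bearing at least one H
#   hba              N or O, excluding amide N
#   aromatic         atoms of aromatic rings

.adjacency <- function(g) {
  n <- length(g$z)
  adj <- vector("list", n)
  for (k in seq_along(g$bfrom)) {
    i <- g$bfrom[k]; j <- g$bto[k]
    adj[[i]] <- rbind(adj[[i]], c(j, g$border[k]))
    adj[[j]] <- rbind(adj[[j]], c(i, g$border[k]))
  }
  adj
}

.acid_carbons <- function(g) {
  adj <- .adjacency(g)
  deg <- vapply(adj, function(a) if (is.null(a)) 0L else nrow(a), integer(1))
  out <- integer(0)
  for (i in which(g$z == 6)) {
    a <- adj[[i]]
    if (is.null(a)) next
    has_dbO <- any(g$z[a[, 1]] == 8 & a[, 2] == 2 & deg[a[, 1]] == 1)
    has_OH <- any(g$z[a[, 1]] == 8 & a[, 2] == 1 & deg[a[, 1]] == 1 &
                    (g$nh[a[, 1]] == 1 | g$charge[a[, 1]] == -1))
    if (has_dbO && has_OH) out <- c(out, i)
  }
  out
}

.amide_pairs <- function(g) {
  # returns matrix with columns (carbonyl C, amide N)
  adj <- .adjacency(g)
  out <- NULL
  for (i in which(g$z == 6)) {
    a <- adj[[i]]
    if (is.null(a)) next
    if (!any(g$z[a[, 1]] == 8 & a[, 2] == 2)) next
    ns <- a[g$z[a[, 1]] == 7 & a[, 2] == 1, 1]
    for (nn in ns) out <- rbind(out, c(i, nn))
  }
  out
}

.sulphone_atoms <- function(g) {
  adj <- .adjacency(g)
  out <- integer(0)
  for (i in which(g$z == 16)) {
    a <- adj[[i]]
    if (!is.null(a) && sum(g$z[a[, 1]] == 8 & a[, 2] == 2) >= 2) out <- c(out, i)
  }
  out
}

.sulfonamide_atoms <- function(g) {
  adj <- .adjacency(g)
  out <- integer(0)
  for (i in .sulphone_atoms(g)) {
    a <- adj[[i]]
    if (any(g$z[a[, 1]] == 7 & a[, 2] == 1)) out <- c(out, i)
  }
  out
}

.aromatic_rings <- function(g) {
  # rings flagged aromatic on the kekulized graph: size 5 or 6, members are
  # C/N/O/S, and every member either carries a ring-internal double bond or is
  # a heteroatom contributing a lone pair (pyrrole N, furan O, thiophene S).
  rings <- .ring_list(g)
  if (length(rings) == 0) return(list())
  out <- list()
  for (r in rings) {
    if (!(length(r) %in% c(5L, 6L))) next
    zs <- g$z[r]
    if (!all(zs %in% c(6, 7, 8, 16))) next
    inr <- g$bfrom %in% r & g$bto %in% r
    pi_atom <- rep(FALSE, length(g$z))
    for (k in which(inr & g$border == 2)) {
      pi_atom[g$bfrom[k]] <- TRUE
      pi_atom[g$bto[k]] <- TRUE
    }
    n_pi <- sum(pi_atom[r])
    if (n_pi >= 2 && all(pi_atom[r] | zs %in% c(7, 8, 16))) {
      out[[length(out) + 1]] <- r
    }
  }
  out
}

.aromatic_atoms <- function(g) {
  if (!is.null(g$arom_atoms)) return(g$arom_atoms)
  sort(unique(unlist(.aromatic_rings(g))))
}

# minimal ring set via iterative shortest-cycle extraction on ring bonds
.ring_list <- function(g) {
  nb <- length(g$bfrom)
  if (nb == 0) return(list())
  if (is.null(g$bond_ring)) {
    ri <- cpp_ring_info(g$z, g$charge, g$nh, g$inring, g$bfrom, g$bto, g$border)
    g$bond_ring <- ri$bond_ring
  }
  rb <- which(g$bond_ring)
  if (length(rb) == 0) return(list())
  n <- length(g$z)
  adj <- vector("list", n)
  for (k in rb) {
    adj[[g$bfrom[k]]] <- c(adj[[g$bfrom[k]]], g$bto[k])
    adj[[g$bto[k]]] <- c(adj[[g$bto[k]]], g$bfrom[k])
  }
  rings <- list()
  seen <- character(0)
  for (k in rb) {
    src <- g$bfrom[k]; dst <- g$bto[k]
    # BFS from src to dst avoiding the direct edge -> smallest ring through bond k
    prev <- rep(NA_integer_, n)
    prev[src] <- 0L
    queue <- src
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (v == src && w == dst) next
        if (is.na(prev[w])) { prev[w] <- v; queue <- c(queue, w) }
      }
      if (!is.na(prev[dst])) break
    }
    if (is.na(prev[dst])) next
    path <- dst
    v <- dst
    while (prev[v] != 0L) { v <- prev[v]; path <- c(path, v) }
    ring <- sort(path)
    key <- paste(ring, collapse = "-")
    if (!(key %in% seen)) { seen <- c(seen, key); rings[[length(rings) + 1]] <- ring }
  }
  rings
}

.n_aromatic_rings <- function(g) {
  if (!is.null(g$arom_rings)) return(length(g$arom_rings))
  length(.aromatic_rings(g))
}

#' Select feature atoms on a molecular graph
#'
#' @param g molecular graph
#' @param feature one of `"carboxylic_acid"`, `"sulphone"`, `"sulfonamide"`,
#'   `"amide"`, `"aromatic"`, `"hba"`, `"hbd"`, or a function(graph) returning
#'   atom indices
#' @return integer vector of (1-based) matching atom indices
#' @export
feature_atoms <- function(g, feature) {
  if (is.function(feature)) return(as.integer(feature(g)))
  switch(match.arg(feature, c("carboxylic_acid", "sulphone", "sulfonamide",
                              "amide", "aromatic", "hba", "hbd")),
    carboxylic_acid = .acid_carbons(g),
    sulphone = .sulphone_atoms(g),
    sulfonamide = .sulfonamide_atoms(g),
    amide = { p <- .amide_pairs(g); if (is.null(p)) integer(0) else unique(p[, 1]) },
    aromatic = .aromatic_atoms(g),
    hbd = which(g$z %in% c(7, 8) & g$nh > 0),
    hba = {
      amide_n <- { p <- .amide_pairs(g); if (is.null(p)) integer(0) else unique(p[, 2]) }
      setdiff(which(g$z %in% c(7, 8)), amide_n)
    })
}
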