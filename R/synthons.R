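# Packaged synthon fragment sets and their parsed/precomputed tables.
#
# The library emulates an amide-coupled, make-on-demand synthon space in the
# style of amino-acid-rich lead-like collections. Three positional sets:
#   acids    R-COOH        (acylating partners; SMILES end with "C(=O)O")
#   centrals H(N)-CHR-COOH (bifunctional cores; start with the coupling N and
#                           end with "C(=O)O")
#   amines   R-NH2         (capping partners; SMILES start with the coupling N)
# Products are two-component acid+amine amides (rule "AC") and
# three-component acid+central+amine bis-amides (rule "ABC"). Because every
# fragment carries its attachment atom at a string boundary, product SMILES
# are formed by concatenation (dropping the leaving hydroxyl "O"), and product
# graphs by concatenating fragment graphs plus the new amide bonds.

.para_subs <- c("C", "F", "Cl", "OC", "N", "O", "CC", "C#N", "CO")

#' Packaged synthon fragment sets
#'
#' @return list with character vectors `acids`, `centrals`, `amines`
#' @export
default_synthon_sets <- function() {
  subs <- .para_subs
  acids <- c(
    sprintf("c1cc(%s)ccc1C(=O)O", subs),
    sprintf("c1oc(%s)cc1C(=O)O", subs),
    sprintf("c1sc(%s)cc1C(=O)O", subs),
    sprintf("c1nc(%s)ccc1C(=O)O", subs),
    sprintf("c1cc(%s)cnc1C(=O)O", subs),
    sprintf("c1cc(%s)ccc1CC(=O)O", subs),
    "CC(=O)O", "CCC(=O)O", "CC(C)C(=O)O", "CC(C)(C)C(=O)O",
    "FC(F)(F)C(=O)O", "FC(F)C(=O)O",
    "C1CC1C(=O)O", "C1CCC1C(=O)O", "C1CCCC1C(=O)O", "C1CCCCC1C(=O)O",
    "C1COC1C(=O)O", "C1CCOC1C(=O)O", "C1CCOCC1C(=O)O", "C1CN(C)CC1C(=O)O",
    "COCC(=O)O", "CSCC(=O)O", "CN(C)CC(=O)O", "OCC(=O)O", "CC(O)C(=O)O",
    "OC(=O)CC(=O)O", "OC(=O)CCC(=O)O", "CC(=O)C(=O)O", "NC(=O)CC(=O)O",
    "c1ccccc1C(=O)O", "c1ccccc1CC(=O)O", "c1ccoc1C(=O)O", "c1ccsc1C(=O)O",
    "c1ccncc1C(=O)O", "Oc1ccccc1C(=O)O", "Nc1ccccc1C(=O)O",
    "COc1ccccc1C(=O)O", "Cn1ccnc1C(=O)O", "Cn1ccc(n1)C(=O)O",
    "c1cnn(C)c1C(=O)O", "Cc1noc(c1)C(=O)O", "CCC(C)C(=O)O", "CC(F)C(=O)O",
    "OCC(O)C(=O)O", "CC(C)OCC(=O)O", "CC(C)(O)C(=O)O", "CC1(CC1)C(=O)O",
    "C1COCC1C(=O)O", "COC(C)C(=O)O", "CS(=O)(=O)CC(=O)O", "NS(=O)(=O)CC(=O)O",
    "CC(=O)NCC(=O)O", "CS(=O)(=O)c1ccc(cc1)C(=O)O",
    "NS(=O)(=O)c1ccc(cc1)C(=O)O", "CC(=O)Nc1ccc(cc1)C(=O)O"
  )
  sides <- c("C", "CC", "CCC", "CC(C)C", "C(C)C", "CO", "CCO", "CC(C)O",
             "COC", "CSC", "CC(=O)O", "CCC(=O)O", "CC(N)=O", "CCC(N)=O",
             "CS(C)(=O)=O", "CS(N)(=O)=O", "CNC(C)=O", "CC#N",
             "Cc1ccccc1", "Cc1ccc(O)cc1", "Cc1ccc(F)cc1", "Cc1ccc(Cl)cc1",
             "Cc1ccc(OC)cc1", "Cc1ccc(C#N)cc1", "Cc1ccc(N)cc1",
             "Cc1ccsc1", "Cc1ccoc1", "Cc1ccncc1", "Cc1cccnc1",
             "CCSC", "CCS(C)(=O)=O", "CCS(N)(=O)=O", "CCNC(C)=O",
             "CCC#N", "CCOC", "CCCO", "Cc1ccc(S(N)(=O)=O)cc1",
             "Cc1ccc(S(C)(=O)=O)cc1", "Cc1ccc(C(N)=O)cc1", "Cc1ccc(NC(C)=O)cc1")
  centrals <- c(
    sprintf("NC(%s)C(=O)O", sides),
    sprintf("N(C)C(%s)C(=O)O", sides),
    sprintf("NC(C)(%s)C(=O)O", sides[1:10]),
    "NCC(=O)O", "NCCC(=O)O", "NCC(C)C(=O)O",
    "N1CCC1C(=O)O", "N1CCCC1C(=O)O", "N1CCCCC1C(=O)O", "N1CCOCC1C(=O)O"
  )
  amines <- c(
    sprintf("NCc1ccc(%s)cc1", subs),
    sprintf("NCCc1ccc(%s)cc1", subs),
    sprintf("Nc1ccc(%s)cc1", subs),
    "NCc1cccc(F)c1", "NCc1cccc(Cl)c1", "NCc1cccc(OC)c1", "NCc1cccc(C)c1",
    "NCCc1cccc(F)c1", "NCCc1cccc(OC)c1", "NCc1cc(F)cc(F)c1",
    "NCc1ccsc1", "NCc1ccoc1", "NCc1ccncc1", "NCc1cccnc1",
    "NCCc1ccsc1", "NCCc1ccncc1", "NCCc1ccoc1",
    "NCc1cnn(C)c1", "NCCn1ccnc1",
    "NC", "NCC", "NCCC", "NCCCC", "NCC(C)C", "NC(C)C", "NC(C)CC",
    "NCC(C)(C)C", "NC1CC1", "NC1CCC1", "NC1CCCC1", "NC1CCCCC1",
    "NCC1CCC1", "NCC1CCCC1",
    "NC1COC1", "NC1CCOC1", "NC1CCOCC1", "NCC1CCOC1", "NCC1CCOCC1",
    "NCC1COC1",
    "NCCO", "NCCCO", "NCCOC", "NCCSC", "NCC(O)C", "NCC(F)F", "NCCF",
    "NCCS(C)(=O)=O", "NCCS(N)(=O)=O", "NCCC#N", "NCCN(C)C", "NCCNC(C)=O",
    "NCC(N)=O", "NCCN1CCOCC1",
    "N1CCOCC1", "N1CCCC1", "N1CCCCC1", "N1CCC1", "N1CCN(C)CC1",
    "N(C)C", "N(C)CC", "N(C)CCO", "N(C)Cc1ccccc1", "N(C)Cc1ccsc1",
    "NCc1ccc(S(C)(=O)=O)cc1", "NCc1ccc(NC(C)=O)cc1", "NCc1ccc(C(N)=O)cc1",
    "NCCOCC", "NCC(O)CO", "NC(C)CO", "NCCCOC", "NCCCC#N", "NCCCN(C)C",
    "NCc1ccc(O)c(OC)c1", "NCc1cc(OC)cc(OC)c1", "NCCc1cc(F)cc(F)c1",
    "NCC1CC1", "NCC(C)O", "NCC(F)(F)F", "N1CCOC1", "N(C)C(C)C",
    "N(C)CCOC", "NC(C)C(N)=O", "NCCc1cnn(C)c1"
  )
  list(acids = unique(acids), centrals = unique(centrals), amines = unique(amines))
}

.water_mw <- 18.01528

# strip the leaving hydroxyl for SMILES concatenation (acid SMILES end "C(=O)O")
.acyl_smiles <- function(s) sub("O$", "", s)

# Parse one fragment set role and annotate junction atoms.
# role: "acid" (acyl end only), "central" (amine + acyl), "amine" (amine only)
.parse_fragments <- function(smiles, role) {
  parsed <- mol_graphs_from_smiles(stats::setNames(smiles, paste0("F", seq_along(smiles))))
  if (length(parsed$failures) > 0) {
    bad <- smiles[match(parsed$failures, paste0("F", seq_along(smiles)))]
    stop("unparseable synthon fragment(s): ", paste(bad, collapse = ", "))
  }
  lapply(seq_along(smiles), function(i) {
    g <- parsed$graphs[[i]]
    n <- length(g$z)
    acyl_c <- 0L; acyl_o <- 0L; amine_n <- 0L
    if (role %in% c("acid", "central")) {
      ac <- .acid_carbons(g)
      if (length(ac) == 0) stop("fragment has no carboxyl group: ", smiles[i])
      # the coupling carboxyl is the one written at the end of the SMILES:
      # its hydroxyl oxygen is the final atom of the parse order
      adj <- .adjacency(g)
      oh <- vapply(ac, function(ci) {
        a <- adj[[ci]]
        max(a[g$z[a[, 1]] == 8 & a[, 2] == 1, 1])
      }, numeric(1))
      pick <- which.max(oh)
      acyl_c <- ac[pick]; acyl_o <- as.integer(oh[pick])
      if (acyl_o != n) stop("acid fragment must end with its carboxyl OH: ", smiles[i])
    }
    if (role %in% c("central", "amine")) {
      if (g$z[1] != 7 || g$nh[1] < 1) {
        stop("amine fragment must start with its coupling N-H: ", smiles[i])
      }
      amine_n <- 1L
    }
    list(z = g$z, charge = g$charge, nh = g$nh, inring = g$inring,
         bfrom = g$bfrom, bto = g$bto, border = g$border,
         acyl_c = acyl_c, acyl_o = acyl_o, amine_n = amine_n, graph = g)
  })
}

# per-fragment descriptor contributions (additive over amide couplings)
.fragment_table <- function(smiles, frags) {
  sdf <- ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("F", seq_along(smiles))))
  props <- ChemmineR::propOB(sdf)
  g_list <- lapply(frags, `[[`, "graph")
  data.frame(
    smiles = smiles,
    mw = props$MW,
    logp = props$logP,
    n_rings = vapply(g_list, .n_rings_graph, integer(1)),
    n_arom = vapply(g_list, .n_aromatic_rings, numeric(1)),
    n_no = vapply(g_list, function(g) sum(g$z %in% c(7L, 8L)), numeric(1)),
    n_acid = vapply(g_list, function(g) length(.acid_carbons(g)), numeric(1)),
    rot = vapply(g_list, function(g) {
      cpp_rotatable_count(g$z, g$charge, g$nh, g$inring, g$bfrom, g$bto, g$border)
    }, integer(1)),
    alpha_corr = vapply(g_list, function(g) {
      # junction rotor correction: the bond N-C alpha becomes rotatable once
      # the terminal coupling N gains its acyl neighbour, provided C alpha is
      # itself non-terminal
      if (g$z[1] != 7) return(0)
      nbrs <- c(g$bto[g$bfrom == 1], g$bfrom[g$bto == 1])
      if (length(nbrs) != 1) return(0)
      deg_alpha <- sum(g$bfrom == nbrs | g$bto == nbrs)
      as.numeric(deg_alpha >= 2)
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
}

# calibrated once per session: the (constant) OpenBabel logP shift of forming
# an amide from a free acid and a free amine
.amide_logp_delta <- function() {
  if (!is.null(.alscreen_cache$amide_logp_delta)) return(.alscreen_cache$amide_logp_delta)
  p <- ChemmineR::propOB(ChemmineR::smiles2sdf(
    c(prod = "CC(=O)NC", acid = "CC(=O)O", amine = "NC")))
  d <- p$logP[1] - p$logP[2] - p$logP[3]
  .alscreen_cache$amide_logp_delta <- d
  d
}

# Parse + precompute everything for a set of synthon lists; cached per session.
.synthon_data <- function(sets) {
  cached <- .alscreen_cache$synthon_data
  if (!is.null(cached) && identical(cached$sets, sets)) return(cached)
  frags_a <- .parse_fragments(sets$acids, "acid")
  frags_b <- .parse_fragments(sets$centrals, "central")
  frags_c <- .parse_fragments(sets$amines, "amine")
  frags <- c(frags_a, frags_b, frags_c)
  tab <- rbind(.fragment_table(sets$acids, frags_a),
               .fragment_table(sets$centrals, frags_b),
               .fragment_table(sets$amines, frags_c))
  out <- list(
    sets = sets,
    n_a = length(sets$acids), n_b = length(sets$centrals), n_c = length(sets$amines),
    off_b = length(sets$acids), off_c = length(sets$acids) + length(sets$centrals),
    frags = lapply(frags, function(f) f[setdiff(names(f), "graph")]),
    graphs = lapply(frags, `[[`, "graph"),
    table = tab,
    acyl_smiles = c(vapply(sets$acids, .acyl_smiles, character(1), USE.NAMES = FALSE),
                    vapply(sets$centrals, .acyl_smiles, character(1), USE.NAMES = FALSE),
                    unname(sets$amines)),
    logp_delta = .amide_logp_delta()
  )
  .alscreen_cache$synthon_data <- out
  out
}

# enumeration-space size for given sets and coupling rules
.space_size <- function(data, rules = c("AC", "ABC")) {
  n <- 0
  if ("AC" %in% rules) n <- n + data$n_a * data$n_c
  if ("ABC" %in% rules) n <- n + data$n_a * data$n_b * data$n_c
  n
}

# decode mixed-radix enumeration indices (0-based) into fragment index triples
# (a, b, c) in the global fragment table; b = 0 marks a two-component product.
.decode_index <- function(k0, data, rules = c("AC", "ABC")) {
  n_pairs <- if ("AC" %in% rules) data$n_a * data$n_c else 0
  a <- integer(length(k0)); b <- integer(length(k0)); c <- integer(length(k0))
  is_pair <- k0 < n_pairs
  if (any(is_pair)) {
    kp <- k0[is_pair]
    a[is_pair] <- kp %/% data$n_c + 1L
    c[is_pair] <- kp %% data$n_c + 1L
    b[is_pair] <- 0L
  }
  if (any(!is_pair)) {
    kt <- k0[!is_pair] - n_pairs
    bc <- data$n_b * data$n_c
    a[!is_pair] <- kt %/% bc + 1L
    r <- kt %% bc
    b[!is_pair] <- r %/% data$n_c + 1L
    c[!is_pair] <- r %% data$n_c + 1L
  }
  cbind(a = as.integer(a), b = as.integer(b), c = as.integer(c))
}

# global fragment-table indices for a decoded composition matrix
.global_comp <- function(comp, data) {
  cbind(a = comp[, 1],
        b = ifelse(comp[, 2] > 0L, comp[, 2] + data$off_b, 0L),
        c = comp[, 3] + data$off_c)
}

# product SMILES by fragment concatenation
.product_smiles <- function(gcomp, data) {
  acyl <- data$acyl_smiles
  mid <- character(nrow(gcomp))
  has_b <- gcomp[, 2] > 0L
  mid[has_b] <- acyl[gcomp[has_b, 2]]
  paste0(acyl[gcomp[, 1]], mid, acyl[gcomp[, 3]])
}
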