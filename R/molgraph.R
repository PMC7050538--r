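#' Hydrogen-suppressed molecular graph
#'
#' Constructs the normative molecule representation used by the fingerprint
#' generator: heavy atoms only, with hydrogens folded into a per-atom
#' `attached_hydrogens` count. Pi-electron counts per atom are derived from
#' the bond list under the convention that a double bond contributes 1 pi
#' electron to each end atom, a triple bond 2, and an aromatic bond 1
#' (a common atom-pair convention; override per atom via a `pi_electrons`
#' column in `atoms` if a different counting is wanted).
#'
#' @param atoms data.frame with columns `element` (symbol, e.g. "C"),
#'   and optionally `formal_charge` (integer, default 0),
#'   `attached_hydrogens` (integer >= 0, default 0) and `pi_electrons`
#'   (integer >= 0; computed from bonds when absent).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (one of "single", "double", "triple", "aromatic"). May have
#'   zero rows.
#' @return an object of class `molecular_graph` with elements `atoms`
#'   (completed data.frame, including derived `heavy_degree`) and `bonds`.
#' @examples
#' propane <- molecular_graph(
#'   atoms = data.frame(element = c("C", "C", "C")),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = "single")
#' )
#' @export
molecular_graph <- function(atoms, bonds = data.frame(i = integer(), j = integer(),
                                                      order = character())) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  if (nrow(atoms) < 1L) stop("a molecular graph needs at least one atom")
  if (is.null(atoms$element)) stop("atoms must have an 'element' column")
  atoms$element <- as.character(atoms$element)
  if (any(toupper(atoms$element) == "H")) {
    stop("hydrogens may not be explicit atoms; use attached_hydrogens")
  }
  if (is.null(atoms$formal_charge)) atoms$formal_charge <- 0L
  if (is.null(atoms$attached_hydrogens)) atoms$attached_hydrogens <- 0L
  atoms$formal_charge <- as.integer(atoms$formal_charge)
  atoms$attached_hydrogens <- as.integer(atoms$attached_hydrogens)
  if (any(atoms$attached_hydrogens < 0L)) stop("attached_hydrogens must be >= 0")

  n <- nrow(atoms)
  if (nrow(bonds) > 0L) {
    if (!all(c("i", "j", "order") %in% names(bonds))) {
      stop("bonds must have columns i, j, order")
    }
    bonds$i <- as.integer(bonds$i)
    bonds$j <- as.integer(bonds$j)
    bonds$order <- as.character(bonds$order)
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n)) {
      stop("bond atom index out of range")
    }
    if (any(bonds$i == bonds$j)) stop("self-bonds are not allowed")
    if (!all(bonds$order %in% c("single", "double", "triple", "aromatic"))) {
      stop("bond order must be one of single, double, triple, aromatic")
    }
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key)) stop("duplicate bond between the same atom pair")
  }

  atoms$heavy_degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  if (is.null(atoms$pi_electrons)) {
    pi_per_bond <- c(single = 0L, double = 1L, triple = 2L, aromatic = 1L)
    contrib <- pi_per_bond[bonds$order]
    pi <- numeric(n)
    if (nrow(bonds) > 0L) {
      for (b in seq_len(nrow(bonds))) {
        pi[bonds$i[b]] <- pi[bonds$i[b]] + contrib[b]
        pi[bonds$j[b]] <- pi[bonds$j[b]] + contrib[b]
      }
    }
    atoms$pi_electrons <- as.integer(pi)
  } else {
    atoms$pi_electrons <- as.integer(atoms$pi_electrons)
    if (any(atoms$pi_electrons < 0L)) stop("pi_electrons must be >= 0")
  }

  structure(list(atoms = atoms, bonds = bonds), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph: %d heavy atoms, %d bonds>\n",
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

n_atoms <- function(graph) nrow(graph$atoms)

check_graph <- function(graph) {
  if (!inherits(graph, "molecular_graph")) {
    stop("expected a molecular_graph object")
  }
  graph
}

check_atom_index <- function(graph, atom_index) {
  if (length(atom_index) != 1L || is.na(atom_index) ||
      atom_index < 1L || atom_index > n_atoms(graph)) {
    stop("atom_index out of range")
  }
  as.integer(atom_index)
}

#' Atom-pair (AP) atom type of one atom
#'
#' AP atom types classify a heavy atom by its element, the number of bonded
#' non-hydrogen neighbours (heavy degree) and its pi-electron count, written
#' canonically as `"El(degree,pi)"`, e.g. the central carbon of propane is
#' `"C(2,0)"`.
#'
#' @param graph a [molecular_graph()].
#' @param atom_index 1-based atom index.
#' @return an object of class `ap_atom_type` with fields `element`,
#'   `heavy_degree`, `pi_electrons`; its `format()`/`as.character()` is the
#'   canonical text form, and [parse_ap_atom_type()] inverts it.
#' @export
ap_atom_type <- function(graph, atom_index) {
  check_graph(graph)
  atom_index <- check_atom_index(graph, atom_index)
  a <- graph$atoms[atom_index, ]
  structure(
    list(element = a$element,
         heavy_degree = a$heavy_degree,
         pi_electrons = a$pi_electrons),
    class = "ap_atom_type"
  )
}

#' @export
format.ap_atom_type <- function(x, ...) {
  sprintf("%s(%d,%d)", x$element, x$heavy_degree, x$pi_electrons)
}

#' @export
as.character.ap_atom_type <- function(x, ...) format(x)

#' @export
print.ap_atom_type <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse the canonical text form of an AP atom type
#'
#' @param text a string such as `"C(2,0)"`.
#' @return an `ap_atom_type` object.
#' @export
parse_ap_atom_type <- function(text) {
  m <- regmatches(text, regexec("^([A-Za-z]+)\\((\\d+),(\\d+)\\)$", text))[[1]]
  if (length(m) != 4L) stop("not a canonical AP atom type: ", text)
  structure(
    list(element = m[2],
         heavy_degree = as.integer(m[3]),
         pi_electrons = as.integer(m[4])),
    class = "ap_atom_type"
  )
}

# Vectorized AP type strings for all atoms of a graph.
ap_type_strings <- function(graph) {
  a <- graph$atoms
  sprintf("%s(%d,%d)", a$element, a$heavy_degree, a$pi_electrons)
}

#' Binding-property (BP) atom type of one atom
#'
#' BP (also called donor-acceptor pair, DP) typing places every heavy atom
#' in exactly one of seven pharmacophoric categories: cation, anion,
#' neutral_donor, neutral_acceptor, polar, hydrophobic, other. The rule
#' table, evaluated in this fixed precedence order, is:
#'
#' 1. formal charge > 0: `cation`
#' 2. formal charge < 0: `anion`
#' 3. N or O atoms: a donor has at least one attached hydrogen; an acceptor
#'    has an available lone pair (O always; N when heavy_degree +
#'    attached_hydrogens <= 3). Donor and acceptor together give `polar`,
#'    donor alone `neutral_donor`, acceptor alone `neutral_acceptor`.
#' 4. carbon and halogens (F, Cl, Br, I): `hydrophobic`
#' 5. everything else (S, P, metals, ...): `other`
#'
#' Under this table a hydroxyl oxygen (one H, one lone pair) is `polar` and
#' an sp3 carbon is `hydrophobic`.
#'
#' @inheritParams ap_atom_type
#' @return a single string, one of the seven category names.
#' @export
bp_atom_type <- function(graph, atom_index) {
  check_graph(graph)
  atom_index <- check_atom_index(graph, atom_index)
  bp_type_strings(graph)[atom_index]
}

bp_type_strings <- function(graph) {
  a <- graph$atoms
  out <- character(nrow(a))
  for (k in seq_len(nrow(a))) {
    el <- a$element[k]
    if (a$formal_charge[k] > 0L) {
      out[k] <- "cation"
    } else if (a$formal_charge[k] < 0L) {
      out[k] <- "anion"
    } else if (el %in% c("N", "O")) {
      donor <- a$attached_hydrogens[k] >= 1L
      acceptor <- el == "O" ||
        (a$heavy_degree[k] + a$attached_hydrogens[k]) <= 3L
      out[k] <- if (donor && acceptor) "polar"
      else if (donor) "neutral_donor"
      else if (acceptor) "neutral_acceptor"
      else "other"
    } else if (el %in% c("C", "F", "Cl", "Br", "I")) {
      out[k] <- "hydrophobic"
    } else {
      out[k] <- "other"
    }
  }
  out
}

#' All-pairs topological distances in bonds
#'
#' Shortest bond-path length between every pair of heavy atoms (breadth-first
#' search on the unweighted bond graph). The matrix is symmetric with a zero
#' diagonal; atom pairs in different connected components are `Inf`.
#'
#' @param graph a [molecular_graph()].
#' @return an `n x n` numeric matrix of bond counts.
#' @export
topological_distances <- function(graph) {
  check_graph(graph)
  n <- n_atoms(graph)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(graph$bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(graph$bonds$i, graph$bonds$j))
  }
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  d
}

fingerprint_key <- function(scheme, type_a, type_b, distance) {
  lo <- pmin(type_a, type_b)
  hi <- pmax(type_a, type_b)
  sprintf("%s|%s|%d|%s", scheme, lo, as.integer(distance), hi)
}

#' Pair-count fingerprint of a molecule
#'
#' Counts, for every unordered pair of heavy atoms whose topological
#' distance d satisfies 1 <= d <= `max_distance`, the descriptor
#' "type_a - d - type_b" with atom types from the AP or BP scheme.
#' Keys are canonical text of the form `"AP|C(1,0)|2|C(2,0)"` (endpoint
#' types sorted lexicographically), suitable as stable CSV column names.
#' For a connected molecule with n heavy atoms and `max_distance` at least
#' the graph diameter, the counts sum to n(n-1)/2.
#'
#' @param graph a [molecular_graph()].
#' @param scheme `"AP"` or `"BP"`.
#' @param max_distance largest bond distance recorded (>= 1); default 7.
#' @return a `fingerprint`: a named integer vector of strictly positive
#'   counts (absent key = count zero), with a `scheme` attribute.
#' @examples
#' propane <- molecular_graph(
#'   atoms = data.frame(element = c("C", "C", "C")),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = "single")
#' )
#' generate_fingerprint(propane, "AP")
#' @export
generate_fingerprint <- function(graph, scheme = c("AP", "BP"), max_distance = 7L) {
  check_graph(graph)
  scheme <- match.arg(scheme)
  max_distance <- as.integer(max_distance)
  if (is.na(max_distance) || max_distance < 1L) stop("max_distance must be >= 1")

  types <- if (scheme == "AP") ap_type_strings(graph) else bp_type_strings(graph)
  n <- n_atoms(graph)
  counts <- integer(0)
  if (n >= 2L) {
    d <- topological_distances(graph)
    keys <- character(0)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        dij <- d[i, j]
        if (is.finite(dij) && dij >= 1 && dij <= max_distance) {
          keys <- c(keys, fingerprint_key(scheme, types[i], types[j], dij))
        }
      }
    }
    if (length(keys) > 0L) {
      tab <- table(keys)
      counts <- as.integer(tab)
      names(counts) <- names(tab)
    }
  }
  new_fingerprint(counts, scheme)
}

new_fingerprint <- function(counts, scheme) {
  if (length(counts) > 0L) counts <- counts[order(names(counts))]
  else counts <- stats::setNames(integer(0), character(0))
  structure(counts, scheme = scheme, class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<%s fingerprint: %d keys, total count %d>\n",
              attr(x, "scheme"), length(x), sum(x)))
  if (length(x) > 0L) {
    print(stats::setNames(as.integer(x), names(x)))
  }
  invisible(x)
}

#' Merge an AP and a BP fingerprint into one unified vector
#'
#' The benchmark's molecular fingerprint is the union of the AP and BP count
#' vectors; the scheme prefix in each key keeps the two vocabularies
#' disjoint, so the merge is a key-disjoint union with additive totals.
#'
#' @param ap a `fingerprint` with scheme `"AP"`.
#' @param bp a `fingerprint` with scheme `"BP"`.
#' @return a `fingerprint` with scheme `"AP+BP"`.
#' @export
merge_fingerprints <- function(ap, bp) {
  if (!inherits(ap, "fingerprint") || !identical(attr(ap, "scheme"), "AP")) {
    stop("'ap' must be a fingerprint with scheme AP")
  }
  if (!inherits(bp, "fingerprint") || !identical(attr(bp, "scheme"), "BP")) {
    stop("'bp' must be a fingerprint with scheme BP")
  }
  if (length(ap) > 0L && !all(startsWith(names(ap), "AP|"))) {
    stop("'ap' contains non-AP keys")
  }
  if (length(bp) > 0L && !all(startsWith(names(bp), "BP|"))) {
    stop("'bp' contains non-BP keys")
  }
  merged <- c(unclass(ap), unclass(bp))
  new_fingerprint(merged, "AP+BP")
}

# Standard-valence implicit hydrogen model used when reading molfiles whose
# hydrogens are implicit. Aromatic bonds count 1.5 toward the valence sum.
standard_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

implicit_hydrogens <- function(element, formal_charge, bond_order_sum) {
  v <- standard_valence[element]
  if (is.na(v)) return(0L)
  # charge raises the valence of N-family cations (N+ binds 4), lowers it
  # for anions (O- binds 1)
  if (element %in% c("N", "P")) v <- v + formal_charge
  if (element %in% c("O", "S")) v <- v + formal_charge
  if (element == "C") v <- v - abs(formal_charge)
  as.integer(max(0, ceiling(v - bond_order_sum)))
}

#' Read molecules from an SDF (MDL molfile V2000) file
#'
#' Parses each record with ChemmineR and converts it to the package's
#' hydrogen-suppressed [molecular_graph()] representation: explicit hydrogen
#' atoms are removed and added to their neighbour's `attached_hydrogens`;
#' remaining implicit hydrogens are filled in from a standard-valence model
#' (aromatic bonds counting 1.5). Atom-line charge codes are honoured.
#'
#' @param path path to an SDF file.
#' @return a named list of `molecular_graph` objects (names from the molfile
#'   title line, or `mol1`, `mol2`, ... when absent).
#' @export
read_sdf <- function(path) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("read_sdf requires the ChemmineR package")
  }
  sdfs <- ChemmineR::read.SDFset(path)
  out <- vector("list", length(sdfs))
  nms <- character(length(sdfs))
  mdl_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L, `4` = 0L,
                  `5` = -1L, `6` = -2L, `7` = -3L)
  order_names <- c(`1` = "single", `2` = "double", `3` = "triple", `4` = "aromatic")
  for (m in seq_along(sdfs)) {
    sdf <- sdfs[[m]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    elements <- sub("_\\d+$", "", rownames(ab))
    charges <- mdl_charge[as.character(ab[, "C6"])]
    charges[is.na(charges)] <- 0L
    na <- length(elements)
    bi <- if (nrow(bb) > 0) as.integer(bb[, "C1"]) else integer(0)
    bj <- if (nrow(bb) > 0) as.integer(bb[, "C2"]) else integer(0)
    bo <- if (nrow(bb) > 0) order_names[as.character(as.integer(bb[, "C3"]))] else character(0)

    is_h <- toupper(elements) == "H"
    heavy_idx <- which(!is_h)
    new_index <- integer(na)
    new_index[heavy_idx] <- seq_along(heavy_idx)

    explicit_h <- integer(length(heavy_idx))
    keep <- !(is_h[bi] | is_h[bj])
    for (b in which(is_h[bi] | is_h[bj])) {
      heavy_end <- if (is_h[bi[b]]) bj[b] else bi[b]
      if (!is_h[heavy_end]) {
        explicit_h[new_index[heavy_end]] <- explicit_h[new_index[heavy_end]] + 1L
      }
    }

    bi2 <- new_index[bi[keep]]
    bj2 <- new_index[bj[keep]]
    bo2 <- bo[keep]

    order_valence <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)
    bos <- numeric(length(heavy_idx))
    for (b in seq_along(bi2)) {
      w <- order_valence[bo2[b]]
      bos[bi2[b]] <- bos[bi2[b]] + w
      bos[bj2[b]] <- bos[bj2[b]] + w
    }

    el_heavy <- elements[heavy_idx]
    ch_heavy <- charges[heavy_idx]
    hyd <- integer(length(heavy_idx))
    for (k in seq_along(heavy_idx)) {
      imp <- implicit_hydrogens(el_heavy[k], ch_heavy[k], bos[k] + explicit_h[k])
      hyd[k] <- explicit_h[k] + imp
    }

    out[[m]] <- molecular_graph(
      atoms = data.frame(element = el_heavy,
                         formal_charge = ch_heavy,
                         attached_hydrogens = hyd,
                         stringsAsFactors = FALSE),
      bonds = data.frame(i = bi2, j = bj2, order = bo2,
                         stringsAsFactors = FALSE)
    )
    hd <- ChemmineR::header(sdf)
    title <- if (length(hd) >= 1 && nzchar(hd[[1]])) hd[[1]] else sprintf("mol%d", m)
    nms[m] <- title
  }
  names(out) <- make.unique(nms)
  out
}

#' Fingerprint a whole SDF file into an MMAC-style descriptor table
#'
#' Convenience wrapper: reads molecules, fingerprints each under the chosen
#' scheme, and assembles the sparse counts into a dense integer matrix whose
#' columns are the union vocabulary (sorted), suitable for
#' [activity_table()] descriptor input.
#'
#' @inheritParams read_sdf
#' @param scheme `"AP"`, `"BP"` or `"merged"` (AP union BP).
#' @param max_distance passed to [generate_fingerprint()].
#' @return an integer matrix, one row per molecule (rownames = molecule
#'   names), one named column per descriptor key.
#' @export
fingerprint_sdf <- function(path, scheme = c("AP", "BP", "merged"), max_distance = 7L) {
  scheme <- match.arg(scheme)
  mols <- read_sdf(path)
  fps <- lapply(mols, function(g) {
    if (scheme == "merged") {
      merge_fingerprints(generate_fingerprint(g, "AP", max_distance),
                         generate_fingerprint(g, "BP", max_distance))
    } else {
      generate_fingerprint(g, scheme, max_distance)
    }
  })
  vocab <- sort(unique(unlist(lapply(fps, names))))
  mat <- matrix(0L, nrow = length(fps), ncol = length(vocab),
                dimnames = list(names(mols), vocab))
  for (m in seq_along(fps)) {
    if (length(fps[[m]]) > 0L) mat[m, names(fps[[m]])] <- as.integer(fps[[m]])
  }
  mat
}
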