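# Independent brute-force oracles and random-input generators for the
# property suites. Deliberately re-derives everything (BFS, pair
# enumeration, key assembly, Pearson correlation) without touching the
# package's fingerprint or metric internals.

# Classic queue-based BFS over an adjacency list; returns bond distances
# from src (Inf where unreachable).
oracle_bfs <- function(n, bond_i, bond_j, src) {
  adj <- vector("list", n)
  for (k in seq_along(bond_i)) {
    adj[[bond_i[k]]] <- c(adj[[bond_i[k]]], bond_j[k])
    adj[[bond_j[k]]] <- c(adj[[bond_j[k]]], bond_i[k])
  }
  dist <- rep(Inf, n)
  dist[src] <- 0
  queue <- src
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.infinite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# Brute-force pair-count fingerprint: enumerate every unordered atom pair,
# take its BFS distance, and accumulate counts into its own key strings.
oracle_fingerprint <- function(graph, scheme, max_distance) {
  n <- nrow(graph$atoms)
  types <- vapply(seq_len(n), function(k) {
    if (scheme == "AP") format(ap_atom_type(graph, k)) else bp_atom_type(graph, k)
  }, character(1))
  counts <- list()
  for (i in seq_len(n)) {
    di <- oracle_bfs(n, graph$bonds$i, graph$bonds$j, i)
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- di[j]
      if (is.finite(d) && d >= 1 && d <= max_distance) {
        ends <- sort(c(types[i], types[j]))
        key <- paste(scheme, ends[1], d, ends[2], sep = "|")
        counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      }
    }
  }
  if (length(counts) == 0) return(integer(0))
  v <- unlist(counts)
  v[order(names(v))]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random chemically-flavoured graph: a random spanning forest plus a few
# extra edges, random elements/charges/hydrogens and bond orders.
random_graph <- function(n_atoms, connected = NA) {
  elements <- sample(c("C", "C", "C", "C", "N", "O", "S", "Cl"), n_atoms,
                     replace = TRUE)
  charge <- sample(c(0L, 0L, 0L, 0L, 0L, 1L, -1L), n_atoms, replace = TRUE)
  hyd <- sample(0:3, n_atoms, replace = TRUE)
  orders <- c("single", "single", "double", "triple", "aromatic")
  bi <- integer(0); bj <- integer(0)
  if (n_atoms >= 2) {
    if (is.na(connected)) connected <- runif(1) < 0.7
    for (v in 2:n_atoms) {
      if (connected || runif(1) < 0.8) {
        bi <- c(bi, sample.int(v - 1L, 1L))
        bj <- c(bj, v)
      }
    }
    n_extra <- sample(0:2, 1)
    for (e in seq_len(n_extra)) {
      pair <- sort(sample.int(n_atoms, 2L))
      if (!any(bi == pair[1] & bj == pair[2])) {
        bi <- c(bi, pair[1]); bj <- c(bj, pair[2])
      }
    }
  }
  molecular_graph(
    atoms = data.frame(element = elements, formal_charge = charge,
                       attached_hydrogens = hyd, stringsAsFactors = FALSE),
    bonds = data.frame(i = bi, j = bj,
                       order = sample(orders, length(bi), replace = TRUE),
                       stringsAsFactors = FALSE)
  )
}

# Random small activity table with the given descriptor names.
random_activity_table <- function(n_rows, descriptor_names, prefix = "M") {
  desc <- matrix(rpois(n_rows * length(descriptor_names), 0.7),
                 nrow = n_rows,
                 dimnames = list(NULL, descriptor_names))
  activity_table(sprintf("%s%04d", prefix, seq_len(n_rows)),
                 rnorm(n_rows, 5, 1), desc)
}

# Small aligned synthetic dataset for fast protocol tests.
tiny_aligned <- function(seed = 1, n_train = 120, n_test = 60, n_desc = 30,
                         noise_sd = 0.1) {
  d <- generate_dataset(synthetic_spec(n_train = n_train, n_test = n_test,
                                       n_descriptors = n_desc,
                                       noise_sd = noise_sd, seed = seed))
  align_vocabularies(d$train, d$test)
}
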