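# Fixtures and independent oracles, built in code at test time.

# Bare structure_model from coordinates (carbon atoms unless specified).
make_model <- function(xyz, chain = "A", resno = NULL, atom = "CA",
                       element = "C", vdw = 1.87) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  atoms <- data.frame(
    atom = rep_len(atom, n), resname = "GLY",
    chain = rep_len(chain, n),
    resno = if (is.null(resno)) seq_len(n) else resno,
    insert = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = rep_len(element, n),
    vdw_radius = rep_len(vdw, n), stringsAsFactors = FALSE
  )
  oligotopo:::new_structure_model(atoms)
}

# Minimal PDB ATOM line (fixed-width).
pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     occ = 1, altloc = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          altloc, resname, chain, resno, x, y, z, occ, 0, element)
}

write_pdb_fixture <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Erdos-Renyi adjacency matrix under a fixed seed.
er_adjacency <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.integer(stats::runif(length(up)) < p)
  a + t(a)
}

# Planted block-model adjacency: blocks of given sizes, edge prob p_in
# within and p_out between blocks.
planted_blocks <- function(sizes, p_in, p_out, seed) {
  set.seed(seed)
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  a <- matrix(0L, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (lab[i] == lab[j]) p_in else p_out
    a[i, j] <- a[j, i] <- as.integer(stats::runif(1) < p)
  }
  list(adjacency = a, labels = lab)
}

# Independent betweenness oracle straight from the definition: BFS shortest
# path counts sigma, then bc(v) = sum over pairs s<t (s,t != v) of
# sigma(s,v) * sigma(v,t) / sigma(s,t) when d(s,v) + d(v,t) = d(s,t).
bc_oracle <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in 1:n) {
    d[s, s] <- 0; sig[s, s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        for (w in which(adj[v, ] == 1)) {
          if (is.infinite(d[s, w])) {
            d[s, w] <- d[s, v] + 1
            nxt <- c(nxt, w)
          }
          if (d[s, w] == d[s, v] + 1) sig[s, w] <- sig[s, w] + sig[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  bc <- numeric(n)
  for (v in 1:n) {
    tot <- 0
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || sig[s, t] == 0) next
      if (d[s, v] + d[v, t] == d[s, t]) {
        tot <- tot + sig[s, v] * sig[v, t] / sig[s, t]
      }
    }
    bc[v] <- tot
  }
  bc
}

# Adjusted Rand index between two labelings.
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Shared slow fixture: one bead trimer per request, memoised across tests.
.trimer_cache <- new.env(parent = emptyenv())
cached_trimer <- function(n, ab, ac, bc, seed) {
  key <- paste(n, ab, ac, bc, seed, sep = "_")
  if (is.null(.trimer_cache[[key]])) {
    .trimer_cache[[key]] <- gen_bead_trimer(n, c(AB = ab, AC = ac, BC = bc),
                                            seed = seed)
  }
  .trimer_cache[[key]]
}
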