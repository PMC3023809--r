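# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own code paths (loops instead
# of vectorized indexing, recursive DFS instead of the frontier expansion).

# triple-loop slice extraction
oracleSlice <- function(arr, axis, index) {
  d <- dim(arr)
  keep <- setdiff(1:3, axis)
  out <- matrix(0, d[keep[1]], d[keep[2]])
  for (a in seq_len(d[keep[1]])) {
    for (b in seq_len(d[keep[2]])) {
      idx <- integer(3)
      idx[axis] <- index
      idx[keep[1]] <- a
      idx[keep[2]] <- b
      out[a, b] <- arr[idx[1], idx[2], idx[3]]
    }
  }
  out
}

# brute-force axis remap: out[idx] = in[idx[order(perm)]]
oracleReorient <- function(arr, perm) {
  d <- dim(arr)[perm]
  out <- array(arr[1], d)
  inv <- order(perm)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    src <- c(i, j, k)[inv]
    out[i, j, k] <- arr[src[1], src[2], src[3]]
  }
  out
}

# recursive DFS descendant set (inclusive), independent of descendants()
oracleDescendants <- function(nodes, id) {
  kids <- nodes$id[!is.na(nodes$parent) & nodes$parent == id]
  sort(as.integer(c(id, unlist(lapply(kids, oracleDescendants,
                                      nodes = nodes)))))
}

# reference LRU simulation over a sequence of plane indices
oracleLru <- function(accesses, capacity) {
  resident <- integer(0)
  reads <- 0L; hits <- 0L
  for (k in accesses) {
    if (k %in% resident) {
      hits <- hits + 1L
      resident <- c(setdiff(resident, k), k)
    } else {
      reads <- reads + 1L
      resident <- c(resident, k)
      if (length(resident) > capacity) resident <- resident[-1L]
    }
  }
  list(reads = reads, hits = hits, resident = resident)
}

# random single-parent hierarchy as a plain node table
randomNodeTable <- function(n, seed) {
  set.seed(seed)
  parent <- c(NA_integer_,
              vapply(seq_len(n - 1), function(i) sample.int(i, 1L), integer(1)))
  data.frame(
    id = seq_len(n),
    abbrev = sprintf("A%02d", seq_len(n)),
    name = sprintf("node %02d", seq_len(n)),
    r = sample.int(256, n, replace = TRUE) - 1L,
    g = sample.int(256, n, replace = TRUE) - 1L,
    b = sample.int(256, n, replace = TRUE) - 1L,
    parent = parent)
}

# hand-built two-layer atlas on a tiny grid with known ids everywhere
tinyAtlas <- function(dims = c(6L, 5L, 4L), seed = 11L) {
  set.seed(seed)
  anatomic <- labelSet(data.frame(
    id = 1:4, abbrev = c("Rt", "La", "Lb", "Lc"),
    name = c("root", "area a", "area b", "area c"),
    r = c(250L, 200L, 150L, 100L), g = c(10L, 60L, 110L, 160L),
    b = c(5L, 55L, 105L, 155L),
    parent = c(NA, 1L, 1L, 2L)), "anatomic")
  functional <- labelSet(data.frame(
    id = c(1L, 7L, 9L), abbrev = c("F", "Fa", "Fb"),
    name = c("fun root", "fun a", "fun b"),
    r = c(0L, 20L, 40L), g = c(0L, 120L, 220L), b = c(255L, 200L, 150L),
    parent = c(NA, 1L, 1L)), "functional")
  ids1 <- array(sample(0:4, prod(dims), replace = TRUE), dims)
  ids2 <- array(sample(c(0L, 1L, 7L, 9L), prod(dims), replace = TRUE), dims)
  ref <- array(runif(prod(dims)), dims)
  newAtlas(list(labelLayer(ids1, anatomic), labelLayer(ids2, functional)),
           reference = imageVolume(ref))
}
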