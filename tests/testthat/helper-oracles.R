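# Independent oracles used across the suite. These share no code with the
# package implementations they check: the aligner is a vectorised pure-R
# Gotoh DP, clustering is brute-force connected components over a full
# edit-distance matrix, and the monophyly oracle enumerates every clade of
# the tree from the edge table.

IUPAC_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
                R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
                B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)

# semi-global affine-gap alignment with free terminal gaps; canonical
# tie-breaking: end cell scanned bottom row (j ascending) then right column
# (i ascending) keeping strictly greater scores; state preference M > F > E;
# gap states reopen (close the gap) as early as possible
oracle_overlap_align <- function(a, b, match = 1, mismatch = -1,
                                 gap_open = 2, gap_extend = 1) {
  A <- IUPAC_BITS[strsplit(toupper(a), "")[[1]]]
  B <- IUPAC_BITS[strsplit(toupper(b), "")[[1]]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- E <- FF <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  E[1, seq_len(m) + 1L] <- 0    # free leading gap in the query
  FF[seq_len(n) + 1L, 1] <- 0   # free leading gap in the reference
  smat <- outer(A, B, function(x, y) ifelse(bitwAnd(x, y) > 0L, match, mismatch))
  for (i in seq_len(n)) {
    FF[i + 1L, 2L:(m + 1L)] <- pmax(FF[i, 2L:(m + 1L)] - gap_extend,
                                    pmax(M[i, 2L:(m + 1L)], E[i, 2L:(m + 1L)]) -
                                      gap_open - gap_extend)
    Vprev <- pmax(M[i, ], E[i, ], FF[i, ])
    M[i + 1L, 2L:(m + 1L)] <- smat[i, ] + Vprev[1L:m]
    G <- pmax(M[i + 1L, ], FF[i + 1L, ])
    t <- G[1L:m] + (0L:(m - 1L)) * gap_extend
    E[i + 1L, 2L:(m + 1L)] <- cummax(t) - gap_open - gap_extend * (1L:m)
  }
  vmax <- function(i, j) max(M[i + 1L, j + 1L], E[i + 1L, j + 1L], FF[i + 1L, j + 1L])
  best <- -Inf; bi <- n; bj <- 0L
  for (j in 0L:m) if (vmax(n, j) > best) { best <- vmax(n, j); bi <- n; bj <- j }
  for (i in 0L:(n - 1L)) if (vmax(i, m) > best) { best <- vmax(i, m); bi <- i; bj <- m }
  pick <- function(i, j) {
    v <- c(M[i + 1L, j + 1L], E[i + 1L, j + 1L], FF[i + 1L, j + 1L])
    if (v[1] >= v[2] && v[1] >= v[3]) "M" else if (v[3] >= v[2]) "F" else "E"
  }
  i <- bi; j <- bj; state <- pick(i, j)
  matches <- 0L; columns <- 0L
  while (i > 0L && j > 0L) {
    if (state == "M") {
      columns <- columns + 1L
      hit <- bitwAnd(A[i], B[j]) > 0L
      if (hit) matches <- matches + 1L
      vd <- M[i + 1L, j + 1L] - (if (hit) match else mismatch)
      state <- if (M[i, j] == vd) "M" else if (FF[i, j] == vd) "F" else "E"
      i <- i - 1L; j <- j - 1L
    } else if (state == "E") {
      columns <- columns + 1L
      reopen <- E[i + 1L, j + 1L] + gap_open + gap_extend
      state <- if (M[i + 1L, j] == reopen) "M" else if (FF[i + 1L, j] == reopen) "F" else "E"
      j <- j - 1L
    } else {
      columns <- columns + 1L
      reopen <- FF[i + 1L, j + 1L] + gap_open + gap_extend
      state <- if (M[i, j + 1L] == reopen) "M" else if (E[i, j + 1L] == reopen) "E" else "F"
      i <- i - 1L
    }
  }
  list(identity = if (columns > 0L) 100 * matches / columns else 0,
       matches = matches, columns = columns, score = best)
}

# brute-force single-linkage partition at Levenshtein distance <= d
oracle_components <- function(seqs, d) {
  n <- length(seqs)
  adj <- utils::adist(seqs) <= d
  comp <- rep(NA_integer_, n); cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    frontier <- s
    while (length(frontier)) {
      comp[frontier] <- cur
      frontier <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
    }
  }
  comp
}

# all clades of a rooted phylo as tip-label sets, by direct recursion over
# the edge table (independent of the package's parent-walk)
oracle_clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(nd) {
    if (nd <= n_tip) return(tree$tip.label[nd])
    unlist(lapply(kids[[as.character(nd)]], rec))
  }
  lapply(seq_len(n_node), rec)
}

# for each query tip: smallest clade containing it and >= 1 reference tip,
# by exhaustive scan over all clades; returns the assigned SH or NA
oracle_monophyly_assign <- function(tree, ref_tips, query_tips) {
  clades <- oracle_clades(tree)
  out <- setNames(rep(NA_character_, length(query_tips)), query_tips)
  for (q in query_tips) {
    cand <- Filter(function(tl) q %in% tl && any(tl %in% names(ref_tips)), clades)
    sizes <- vapply(cand, length, integer(1))
    smallest <- cand[[which.min(sizes)]]
    shs <- unique(ref_tips[intersect(smallest, names(ref_tips))])
    if (length(shs) == 1L) out[q] <- shs
  }
  out
}

random_dna_string <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                       collapse = "")

mutate_string <- function(seq, n_sub) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample.int(length(ch), n_sub)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}
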