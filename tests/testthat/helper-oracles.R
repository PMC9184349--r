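## Independent brute-force oracles used to validate the fast implementations.

## all permutations of 1..n (n! rows)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

## patristic distances by naive per-pair path walking over the edge list
pathDistOracle <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  parent <- integer(nn)
  plen <- numeric(nn)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    plen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  pathToRoot <- function(v) {
    nodes <- v
    while (parent[v] != 0) {
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    nodes
  }
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(nt - 1)) {
    pi <- pathToRoot(i)
    for (j in (i + 1):nt) {
      pj <- pathToRoot(j)
      mrca <- intersect(pi, pj)[1]
      up <- function(v) {
        s <- 0
        while (v != mrca) {
          s <- s + plen[v]
          v <- parent[v]
        }
        s
      }
      d[i, j] <- d[j, i] <- up(i) + up(j)
    }
  }
  d
}

## exhaustive O(n^2) scans
mntdOracle <- function(f, d) {
  idx <- which(f > 0)
  if (length(idx) < 2) return(NA_real_)
  fr <- f[idx] / sum(f[idx])
  tot <- 0
  for (a in seq_along(idx)) {
    best <- Inf
    for (b in seq_along(idx)) {
      if (a != b && d[idx[a], idx[b]] < best) best <- d[idx[a], idx[b]]
    }
    tot <- tot + fr[a] * best
  }
  unname(tot)
}

bmntdOracle <- function(fk, fl, d) {
  ik <- which(fk > 0); il <- which(fl > 0)
  frk <- fk[ik] / sum(fk[ik]); frl <- fl[il] / sum(fl[il])
  s1 <- 0
  for (a in seq_along(ik)) s1 <- s1 + frk[a] * min(d[ik[a], il])
  s2 <- 0
  for (b in seq_along(il)) s2 <- s2 + frl[b] * min(d[il[b], ik])
  unname(0.5 * (s1 + s2))
}

## exact null distribution of the Raup-Crick null community for a tiny pool:
## all species subsets of size r (sequential weighted draw without
## replacement) x all multinomial fills; returns communities and probs.
## Supports r <= 3 (permutation sum over subset orderings).
enumerateRcNulls <- function(richness, total, occ, ab) {
  S <- length(occ)
  p <- occ / sum(occ)
  subsets <- combn(S, richness)
  out <- list()
  fills <- function(extra, r) {
    if (r == 1) return(matrix(extra, 1, 1))
    grid <- expand.grid(rep(list(0:extra), r - 1))
    grid <- grid[rowSums(grid) <= extra, , drop = FALSE]
    as.matrix(cbind(grid, extra - rowSums(grid)))
  }
  for (ci in seq_len(ncol(subsets))) {
    s <- subsets[, ci]
    perms <- allPermutations(richness)
    pSub <- 0
    for (r in seq_len(nrow(perms))) {
      ord <- s[perms[r, ]]
      pr <- 1
      rem <- 1
      for (v in ord) {
        pr <- pr * p[v] / rem
        rem <- rem - p[v]
      }
      pSub <- pSub + pr
    }
    extra <- total - richness
    q <- ab[s] / sum(ab[s])
    fl <- fills(extra, richness)
    for (r in seq_len(nrow(fl))) {
      x <- integer(S)
      x[s] <- 1L + as.integer(fl[r, ])
      pFill <- stats::dmultinom(fl[r, ], extra, q)
      out[[length(out) + 1L]] <- list(comm = x, prob = pSub * pFill)
    }
  }
  comms <- do.call(rbind, lapply(out, `[[`, "comm"))
  probs <- vapply(out, `[[`, numeric(1), "prob")
  stopifnot(abs(sum(probs) - 1) < 1e-9)
  list(comms = comms, probs = probs)
}

## exact RCbray for a pair given the two enumerated null distributions
exactRcBray <- function(obsBC, nullK, nullL) {
  pl <- 0
  pe <- 0
  for (a in seq_len(nrow(nullK$comms))) {
    for (b in seq_len(nrow(nullL$comms))) {
      bc <- brayCurtis(nullK$comms[a, ], nullL$comms[b, ])
      w <- nullK$probs[a] * nullL$probs[b]
      if (bc < obsBC) pl <- pl + w
      else if (bc == obsBC) pe <- pe + w
    }
  }
  2 * (pl + 0.5 * pe - 0.5)
}

## sign changes of a numeric sequence (zeros ignored)
countSignChanges <- function(v, tol = 1e-10) {
  s <- sign(v[abs(v) > tol])
  sum(diff(s) != 0)
}
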