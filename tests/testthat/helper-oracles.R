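# Independent reference implementations ("oracles") used to validate the
# package's algorithms. These deliberately use different algorithmic
# strategies than the production code.

# -- exact assignment by permutation enumeration ------------------------------
bf_assignment_cost <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(0)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- Inf
  for (pr in perms(seq_len(n))) {
    best <- min(best, sum(cost[cbind(seq_len(n), pr)]))
  }
  best
}

# -- brute-force p-Wasserstein via partial injective matchings ----------------
# every point of d1 is matched to an unused point of d2 or to the diagonal;
# unmatched d2 points also pay their diagonal cost.
bf_wasserstein <- function(d1, d2, p = 2) {
  b1 <- d1$birth; h1 <- d1$death
  b2 <- d2$birth; h2 <- d2$death
  n1 <- length(b1); n2 <- length(b2)
  ddiag <- function(b, h) ((h - b) / sqrt(2))^p
  rec <- function(i, used2) {
    if (i > n1) {
      rest <- setdiff(seq_len(n2), used2)
      return(if (length(rest)) sum(ddiag(b2[rest], h2[rest])) else 0)
    }
    best <- ddiag(b1[i], h1[i]) + rec(i + 1L, used2)
    for (j in setdiff(seq_len(n2), used2)) {
      cst <- (sqrt((b1[i] - b2[j])^2 + (h1[i] - h2[j])^2))^p
      best <- min(best, cst + rec(i + 1L, c(used2, j)))
    }
    best
  }
  rec(1L, integer(0))^(1 / p)
}

# -- level-by-level union oracle for cyclic 0-dim sublevel persistence --------
# recomputes the sublevel components from scratch at every level and matches
# them against the previous level's components; no union-find.
oracle_cyclic_pd <- function(f) {
  n <- length(f)
  if (n == 1L) return(data.frame(birth = f, death = f))
  enext <- c(seq_len(n)[-1L], 1L)
  components_at <- function(a) {
    verts <- which(f <= a)
    lab <- setNames(verts, verts)
    edges <- which(pmax(f, f[enext]) <= a)
    repeat {
      changed <- FALSE
      for (e in edges) {
        u <- as.character(e); w <- as.character(enext[e])
        if (lab[u] != lab[w]) {
          m <- min(lab[u], lab[w])
          lab[lab == lab[u] | lab == lab[w]] <- m
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    split(verts, lab)
  }
  canonical <- function(vs) vs[order(f[vs], vs)][1L]
  prev <- list()   # list of list(vertices, birth)
  births <- numeric(0); deaths <- numeric(0)
  for (a in sort(unique(f))) {
    cur <- components_at(a)
    nxt <- list()
    for (C in cur) {
      inside <- Filter(function(pc) all(pc$vertices %in% C), prev)
      if (length(inside) == 0L) {
        nxt[[length(nxt) + 1L]] <- list(vertices = C, birth = a)
      } else {
        bs <- vapply(inside, function(pc) pc$birth, numeric(1))
        cv <- vapply(inside, function(pc) canonical(pc$vertices), numeric(1))
        surv <- order(bs, cv)[1L]
        for (k in seq_along(inside)) {
          if (k != surv && inside[[k]]$birth < a) {
            births <- c(births, inside[[k]]$birth)
            deaths <- c(deaths, a)
          }
        }
        nxt[[length(nxt) + 1L]] <- list(vertices = C, birth = bs[surv])
      }
    }
    prev <- nxt
  }
  births <- c(births, min(f))
  deaths <- c(deaths, max(f))
  ord <- order(births, deaths)
  data.frame(birth = births[ord], death = deaths[ord])
}

# -- naive agglomerative clustering oracle ------------------------------------
# maintains explicit member lists and recomputes every pairwise linkage value
# from first principles each step; written independently of hca().
oracle_hca_merges <- function(m, linkage) {
  n <- nrow(m)
  sse_med <- function(S) {
    S <- sort(S)
    if (length(S) == 1L) return(0)
    tots <- vapply(S, function(i) sum(m[i, S]), numeric(1))
    med <- S[which.min(tots)]
    sum(m[S, med]^2)
  }
  link <- function(A, B) {
    cross <- as.vector(m[A, B])
    switch(linkage,
      average = mean(cross),
      single = min(cross),
      complete = max(cross),
      ward = sse_med(c(A, B)) - sse_med(A) - sse_med(B))
  }
  clusters <- lapply(seq_len(n), function(i) i)   # id -> members
  ids <- seq_len(n)
  out <- NULL
  for (step in seq_len(n - 1L)) {
    cand <- t(combn(sort(ids), 2L))
    d <- apply(cand, 1L, function(pr) {
      link(clusters[[pr[1L]]], clusters[[pr[2L]]])
    })
    pick <- order(d, cand[, 1L], cand[, 2L])[1L]
    a <- cand[pick, 1L]; b <- cand[pick, 2L]
    newid <- n + step
    clusters[[newid]] <- c(clusters[[a]], clusters[[b]])
    ids <- c(setdiff(ids, c(a, b)), newid)
    out <- rbind(out, c(a = a, b = b, height = d[pick], id = newid))
  }
  as.data.frame(out)
}

# -- literal seed-walk purity oracle ------------------------------------------
# walks upward from a given starting member until the subtree covers c1.
oracle_purity_walk <- function(c1_idx, tree, start) {
  n <- tree$n
  mem <- c(as.list(seq_len(n)), vector("list", n - 1L))
  for (s in seq_len(n - 1L)) {
    mem[[n + s]] <- c(mem[[tree$merges$a[s]]], mem[[tree$merges$b[s]]])
  }
  parent_of <- function(id) {
    s <- which(tree$merges$a == id | tree$merges$b == id)
    if (length(s) == 0L) NA_integer_ else tree$merges$id[s[1L]]
  }
  node <- start
  while (!all(c1_idx %in% mem[[node]])) {
    node <- parent_of(node)
    if (is.na(node)) return(0)
  }
  O <- mem[[node]]
  min(max((n - length(O)) / (n - length(c1_idx)), 0), 1)
}
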