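# Independent brute-force oracles. These deliberately re-derive each
# quantity by exhaustive enumeration, sharing no code path with the
# implementations they check.

# -- local profile-HMM forward score by complete path enumeration ---------
# Sums model/background odds over every (start position, entry state, state
# path, exit state) combination of the local model: entry B->M_j uniform
# 1/L, exit from M_j with probability 1/(L-j+1) scaling the remaining
# transitions, uniform prior over the n start positions.
oracleForwardBits <- function(hmm, seq) {
  odds <- sweep(hmm@matchEmissions, 2, hmm@background, "/")
  tm <- hmm@transitions
  x <- GPCRome:::digitizeAA(seq) + 1L
  n <- length(x)
  L <- nrow(odds)
  pend <- 1 / (L - seq_len(L) + 1)
  em <- function(j, i) if (x[i] >= 21L) 1 else odds[j, x[i]]
  total <- 0
  fromM <- function(i, j, w) {
    total <<- total + w * pend[j]
    keep <- 1 - pend[j]
    if (keep <= 0) return(invisible())
    if (j < L && i < n) fromM(i + 1, j + 1, w * keep * tm[j, "MM"] * em(j + 1, i + 1))
    if (i < n) fromI(i + 1, j, w * keep * tm[j, "MI"])
    if (j < L) fromD(i, j + 1, w * keep * tm[j, "MD"])
  }
  fromI <- function(i, j, w) {
    if (j < L && i < n) fromM(i + 1, j + 1, w * tm[j, "IM"] * em(j + 1, i + 1))
    if (i < n) fromI(i + 1, j, w * tm[j, "II"])
  }
  fromD <- function(i, j, w) {
    # in D_j after the silent step that entered it
    if (j < L && i < n) fromM(i + 1, j + 1, w * tm[j, "DM"] * em(j + 1, i + 1))
    if (j < L) fromD(i, j + 1, w * tm[j, "DD"])
  }
  for (i in seq_len(n)) for (j in seq_len(L)) fromM(i, j, (1 / L) * em(j, i))
  as.numeric(log2(total / n))
}

# -- optimal local alignment score by exhaustive extension ----------------
# Explores every gapped local alignment (affine: first gap residue costs
# open + ext, continuation ext) from every start pair, tracking the best
# prefix score; the empty alignment scores 0.
oracleSWScore <- function(q, s, sub, open = 11, ext = 1) {
  qc <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  m <- length(qc)
  n <- length(sv)
  best <- 0
  rec <- function(i, j, acc, last) {
    if (acc > best) best <<- acc
    if (i <= m && j <= n) rec(i + 1, j + 1, acc + sub[qc[i], sv[j]], "M")
    if (i <= m) rec(i + 1, j, acc - (if (last == "Q") ext else open + ext), "Q")
    if (j <= n) rec(i, j + 1, acc - (if (last == "S") ext else open + ext), "S")
  }
  for (i in seq_len(m)) for (j in seq_len(n)) rec(i, j, 0, "none")
  best
}

# -- motif matching by window enumeration ---------------------------------
# Tests every (start, length) window for an exact full-pattern match by
# direct recursion over the token list, then applies the leftmost-first,
# shortest-at-each-start, non-overlapping selection rule.
oracleMotifScan <- function(region, motif) {
  tokens <- GPCRome:::.parseMotif(motif)  # parsing is shared; matching is not
  chars <- strsplit(toupper(region), "")[[1]]
  fullMatch <- function(win, tks) {
    if (!length(tks)) return(length(win) == 0)
    tok <- tks[[1]]
    if (tok$type == "gap") {
      for (g in tok$min:tok$max) {
        if (g <= length(win) &&
            fullMatch(win[-seq_len(g)], tks[-1])) return(TRUE)
        if (g == length(win) && length(tks) == 1) return(TRUE)
      }
      return(FALSE)
    }
    if (!length(win)) return(FALSE)
    ok <- if (tok$type == "any") TRUE else win[1] %in% tok$set
    ok && fullMatch(win[-1], tks[-1])
  }
  hits <- list()
  p <- 1L
  while (p <= length(chars)) {
    found <- FALSE
    for (len in 1:(length(chars) - p + 1L)) {
      if (fullMatch(chars[p:(p + len - 1L)], tokens)) {
        hits[[length(hits) + 1L]] <- c(p, len)
        p <- p + len
        found <- TRUE
        break
      }
    }
    if (!found) p <- p + 1L
  }
  if (!length(hits)) {
    return(data.frame(offset = integer(0), length = integer(0)))
  }
  m <- do.call(rbind, hits)
  data.frame(offset = m[, 1], length = m[, 2])
}

# -- Dollo minimum by exhaustive event-set search -------------------------
# Minimum number of losses over every single-origin placement: all origin
# branches are tried, and for each, all subsets of candidate loss branches
# (branches under the origin whose clade holds no present tip -- any other
# loss is inconsistent outright). Returns the minimum, or Inf if no
# placement is consistent.
oracleDolloMin <- function(tree, present, absent) {
  nmax <- max(tree$edge)
  ntip <- length(tree$tip.label)
  par <- rep(NA_integer_, nmax)
  par[tree$edge[, 2]] <- tree$edge[, 1]
  ancestors <- function(nd) {
    out <- integer(0)
    while (!is.na(par[nd])) {
      out <- c(out, nd)   # the branch above nd, identified by nd
      nd <- par[nd]
    }
    c(out, nd)
  }
  ancList <- lapply(seq_len(nmax), ancestors)
  tipsUnderNode <- function(nd)
    which(vapply(seq_len(ntip), function(t) nd %in% ancList[[t]], TRUE))
  pres <- match(present, tree$tip.label)
  absn <- match(absent, tree$tip.label)
  best <- Inf
  for (origin in seq_len(nmax)) {
    underT <- tipsUnderNode(origin)
    if (!all(pres %in% underT)) next
    strictlyUnder <- setdiff(
      which(vapply(seq_len(nmax), function(nd)
        nd != origin && origin %in% ancList[[nd]], TRUE)), origin)
    cand <- strictlyUnder[vapply(strictlyUnder, function(nd)
      !any(tipsUnderNode(nd) %in% pres), TRUE)]
    k <- length(cand)
    if (k > 16) stop("oracle tree too large")
    subsets <- 0:(2^k - 1)
    mask <- vapply(seq_len(ntip), function(t) {
      onPath <- intersect(ancList[[t]], cand)
      sum(2^(match(onPath, cand) - 1))
    }, numeric(1))
    consistent <- rep(TRUE, length(subsets))
    for (t in pres) consistent <- consistent & bitwAnd(subsets, mask[t]) == 0
    for (t in intersect(absn, underT))
      consistent <- consistent & bitwAnd(subsets, mask[t]) != 0
    if (any(consistent)) {
      pc <- subsets[consistent]
      nl <- vapply(pc, function(s) sum(bitwAnd(s, 2^(0:max(0, k - 1))) > 0),
                   numeric(1))
      if (k == 0) nl <- 0
      best <- min(best, min(nl))
    }
  }
  best
}
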