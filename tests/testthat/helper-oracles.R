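# Reference implementations used as independent oracles. All are plain,
# slow, string-based R code with no shared machinery with the package's
# compiled path.

rc_ref <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

canon_ref <- function(w) {
  r <- rc_ref(w)
  if (r < w) r else w
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

windows_ref <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  vapply(seq_len(L - k + 1), function(o) substr(s, o, o + k - 1), "")
}

is_acgt <- function(w) !grepl("[^ACGT]", w)

# ---- reference third-pass greedy correction -------------------------------
# Operates on an exact set of canonical k-mer words (character vector).

ref_in_B <- function(w, B) is_acgt(w) && canon_ref(w) %in% B

ref_stretch <- function(s, i, k, B) {
  L <- nchar(s)
  W <- L - k + 1
  cnt <- 0
  o <- i
  while (o <= W && cnt < k) {
    if (!ref_in_B(substr(s, o, o + k - 1), B)) return(cnt)
    cnt <- cnt + 1
    o <- o + 1
  }
  if (cnt >= k) return(cnt)
  suf <- substr(s, L - k + 2, L)
  while (cnt < k) {
    hits <- Filter(function(b) ref_in_B(paste0(suf, b), B),
                   c("A", "C", "G", "T"))
    if (length(hits) != 1) break
    cnt <- cnt + 1
    suf <- paste0(substr(suf, 2, k - 1), hits[[1]])
  }
  cnt
}

ref_anchor <- function(s, k, B) {
  W <- nchar(s) - k + 1
  if (W < 1) return(NULL)
  inb <- vapply(seq_len(W), function(o) ref_in_B(substr(s, o, o + k - 1), B),
                TRUE)
  best <- c(0, 0)  # start, len
  run <- 0
  for (o in seq_len(W)) {
    run <- if (inb[o]) run + 1 else 0
    if (run > best[2]) best <- c(o - run + 1, run)
  }
  if (best[2] == 0) NULL else c(best[1], best[1] + best[2] - 1)
}

ref_weight <- function(orig, qual, p, cutoff) {
  b <- substr(orig, p, p)
  if (!b %in% c("A", "C", "G", "T")) return(0)
  if (!is.null(qual) && is.finite(cutoff) &&
      (utf8ToInt(substr(qual, p, p)) - 33) <= cutoff) return(0.5)
  1
}

ref_budget_ok <- function(wts, L, k, p, w, limit) {
  for (s0 in max(1, p - k + 1):min(p, L - k + 1)) {
    if (sum(wts[s0:min(L, s0 + k - 1)]) + w > limit) return(FALSE)
  }
  TRUE
}

# rightward walk on working string s; map_pos translates s-positions to
# original-orientation positions; map_base translates bases
ref_walk <- function(s, start_w, k, B, orig, qual, cutoff, limit, wts, fwd) {
  L <- nchar(s)
  W <- L - k + 1
  edits <- list()
  ambig <- integer(0)
  budget_stop <- FALSE
  i <- start_w
  while (i <= W) {
    if (ref_in_B(substr(s, i, i + k - 1), B)) { i <- i + 1; next }
    pos <- i + k - 1
    opos <- if (fwd) pos else L + 1 - pos
    scores <- vapply(c("A", "C", "G", "T"), function(b) {
      s2 <- s
      substr(s2, pos, pos) <- b
      ref_stretch(s2, i, k, B)
    }, numeric(1))
    mx <- max(scores)
    winners <- names(scores)[scores == mx]
    if (length(winners) == 1 && mx >= 1 &&
        winners != substr(s, pos, pos)) {
      w <- ref_weight(orig, qual, opos, cutoff)
      if (!ref_budget_ok(wts, L, k, opos, w, limit)) {
        budget_stop <- TRUE
        break
      }
      from <- substr(s, pos, pos)
      substr(s, pos, pos) <- winners
      wts[opos] <- wts[opos] + w
      edits[[length(edits) + 1]] <- list(
        pos = opos,
        from = if (fwd) from else rc_ref(from),
        to = if (fwd) winners else rc_ref(winners)
      )
    } else {
      ambig <- c(ambig, opos)
      i <- i + k
    }
  }
  list(s = s, edits = edits, ambig = ambig, wts = wts,
       budget_stop = budget_stop)
}

ref_correct_read <- function(seq, B, k, qual = NULL, cutoff = -Inf,
                             limit = 4) {
  L <- nchar(seq)
  if (L < k) return(list(seq = seq, edits = list(), ambig = integer(0),
                         anchored = FALSE, budget_stop = FALSE))
  a <- ref_anchor(seq, k, B)
  if (is.null(a)) return(list(seq = seq, edits = list(), ambig = integer(0),
                              anchored = FALSE, budget_stop = FALSE))
  orig <- seq
  wts <- rep(0, L)
  edits <- list()
  ambig <- integer(0)
  budget_stop <- FALSE
  W <- L - k + 1
  if (a[2] + 1 <= W) {
    r <- ref_walk(seq, a[2] + 1, k, B, orig, qual, cutoff, limit, wts,
                  fwd = TRUE)
    seq <- r$s; wts <- r$wts; edits <- c(edits, r$edits)
    ambig <- c(ambig, r$ambig); budget_stop <- budget_stop || r$budget_stop
  }
  if (a[1] > 1) {
    rcs <- rc_ref(seq)
    # weights/qualities are looked up in original orientation inside ref_walk
    start_w <- (W - a[1] + 1) + 1
    r <- ref_walk(rcs, start_w, k, B, orig, qual, cutoff, limit, wts,
                  fwd = FALSE)
    seq <- rc_ref(r$s); wts <- r$wts; edits <- c(edits, r$edits)
    ambig <- c(ambig, r$ambig); budget_stop <- budget_stop || r$budget_stop
  }
  list(seq = seq, edits = edits, ambig = ambig, anchored = TRUE,
       budget_stop = budget_stop)
}

# exact-set filter over the package interface, built from explicit words
exact_set_of <- function(words) {
  s <- kmer_hashset()
  if (length(words)) kmer_set_add(s, words)
  s
}

# canonical k-mer words of a sequence (reference path)
genome_kmers_ref <- function(g, k) {
  unique(vapply(windows_ref(g, k), canon_ref, ""))
}
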