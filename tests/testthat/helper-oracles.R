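# Brute-force reference implementations ("oracles") used to validate the
# package's optimized numerical kernels. These are written directly from the
# defining formulas, with no attention to speed, and must stay independent of
# the package internals they check.

# Sample entropy (Richman & Moorman): templates are the first N - m windows
# of length m; B counts ordered pairs i < j whose Chebyshev distance is
# strictly below r; A counts the same pairs extended to length m + 1.
oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  if (nt < 2) return(NA_real_)
  cheb <- function(i, j, len)
    max(abs(x[i:(i + len - 1)] - x[j:(j + len - 1)]))
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (cheb(i, j, m) < r) {
        B <- B + 1L
        if (i + m <= n && j + m <= n && cheb(i, j, m + 1) < r) A <- A + 1L
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Approximate entropy (Pincus): phi(m) is the average over all N - m + 1
# templates of log(C_i), where C_i is the fraction of templates within
# tolerance r (<=, self-matches included); ApEn = phi(m) - phi(m + 1).
oracle_apen <- function(x, m, r) {
  phi <- function(mm) {
    n <- length(x)
    nt <- n - mm + 1
    tmpl <- sapply(seq_len(nt), function(i) x[i:(i + mm - 1)])
    tmpl <- matrix(tmpl, nrow = mm)
    ci <- vapply(seq_len(nt), function(i) {
      d <- apply(abs(tmpl - tmpl[, i]), 2, max)
      mean(d <= r)
    }, 0.0)
    mean(log(ci))
  }
  phi(m) - phi(m + 1)
}

# LZ76 exhaustive-history phrase count, straight from the definition: extend
# the current phrase while it occurs as a substring of all symbols before the
# phrase's final position; a phrase closes at the first innovative symbol.
oracle_lz76 <- function(b) {
  n <- length(b)
  s <- paste(b, collapse = "")
  cc <- 0L
  i <- 1L
  while (i <= n) {
    l <- 1L
    # grow l while b[i..i+l-1] appears in b[1..i+l-2]
    while (i + l - 1L <= n) {
      sub <- substr(s, i, i + l - 1L)
      hist <- substr(s, 1, i + l - 2L)
      if (!grepl(sub, hist, fixed = TRUE)) break
      l <- l + 1L
    }
    cc <- cc + 1L
    i <- i + l
  }
  cc
}

# Natural visibility graph edges by the O(n^3) definition: a < b are
# connected iff every intermediate point lies strictly below the chord.
oracle_nvg_edges <- function(t, y) {
  n <- length(t)
  out <- NULL
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      vis <- TRUE
      if (b > a + 1) {
        for (c in (a + 1):(b - 1)) {
          ybar <- y[b] + (y[a] - y[b]) * (t[b] - t[c]) / (t[b] - t[a])
          if (y[c] >= ybar) { vis <- FALSE; break }
        }
      }
      if (vis) out <- rbind(out, c(a, b))
    }
  }
  out
}

# Cohen's kappa straight from the definition.
oracle_kappa <- function(truth, pred) {
  cls <- union(unique(truth), unique(pred))
  cm <- table(factor(truth, cls), factor(pred, cls))
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  (po - pe) / (1 - pe)
}

# AUC by exhaustive pair counting (ties count 1/2).
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Convert a vis_graph to an igraph object (igraph is a Suggests-only oracle).
as_igraph <- function(g) {
  igraph::graph_from_edgelist(g$edges, directed = FALSE)
}
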