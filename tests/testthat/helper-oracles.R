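# Independent oracles used across the suite. Deliberately written with
# naive loops and string comparisons, not by calling package internals.

comp_base <- function(ch) {
  switch(ch, A = "T", C = "G", G = "C", T = "A",
         stop("bad base ", ch))
}

rc_manual <- function(s) {
  chs <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(rev(vapply(chs, comp_base, "")), collapse = "")
}

# slide every 6/7/8-nt window over the target, string-compare against the
# four canonical patterns, then keep the most specific site per core locus
oracle_seed_sites <- function(mirna, target) {
  m <- chartr("U", "T", toupper(mirna))
  t_seq <- chartr("U", "T", toupper(target))
  core6 <- rc_manual(substr(m, 2, 7))
  m8_7 <- rc_manual(substr(m, 2, 8))
  a1_7 <- paste0(core6, "A")
  full8 <- paste0(m8_7, "A")
  n <- nchar(t_seq)
  hits <- list()
  for (s in seq_len(n)) {
    w8 <- if (s + 7 <= n) substr(t_seq, s, s + 7) else ""
    w7 <- if (s + 6 <= n) substr(t_seq, s, s + 6) else ""
    w6 <- if (s + 5 <= n) substr(t_seq, s, s + 5) else ""
    if (w8 == full8) {
      hits[[length(hits) + 1]] <-
        list(core = s + 1, type = "8mer-A1", start = s, end = s + 7)
    } else if (w7 == m8_7) {
      hits[[length(hits) + 1]] <-
        list(core = s + 1, type = "7mer-m8", start = s, end = s + 6)
    } else if (w7 == a1_7) {
      hits[[length(hits) + 1]] <-
        list(core = s, type = "7mer-A1", start = s, end = s + 6)
    }
    if (w6 == core6) {
      hits[[length(hits) + 1]] <-
        list(core = s, type = "6mer", start = s, end = s + 5)
    }
  }
  if (!length(hits)) {
    return(data.frame(site_type = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(hits, function(h) {
    data.frame(core = h$core, site_type = h$type, start = h$start,
               end = h$end, stringsAsFactors = FALSE)
  }))
  # most specific (widest) site per core locus
  keep <- do.call(rbind, lapply(split(df, df$core), function(g) {
    g[which.max(g$end - g$start), , drop = FALSE]
  }))
  keep <- keep[order(keep$start), c("site_type", "start", "end")]
  rownames(keep) <- NULL
  keep
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# random target that carries the miRNA's core seed complement at a random
# interior position, so oracle comparisons exercise genuine sites (pure
# random 40-200mers rarely contain a given 6mer)
random_target_with_core <- function(mirna, len) {
  m <- chartr("U", "T", toupper(mirna))
  core <- rc_manual(substr(m, 2, 7))
  left <- sample(1:(len - 8), 1)
  paste0(random_seq(left), core, random_seq(len - left - 6))
}

# full 2^n enumeration of the signed-rank null: every sign assignment of
# the (mid)ranks, two-sided symmetric p
oracle_wilcoxon_exact <- function(case, control) {
  d <- case - control
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# direct recomputation of hit classes from raw signals with plain loops
oracle_classify <- function(signals, dropout_max = 0.2, retained_min = 5,
                            cv_max = 60) {
  ids <- unique(signals$mirna_id)
  out <- character(length(ids))
  names(out) <- ids
  for (id in ids) {
    cls <- "filtered"
    ok <- TRUE
    means <- c(control = NA, treated = NA)
    for (cond in c("control", "treated")) {
      x <- signals$signal[signals$mirna_id == id & signals$condition == cond]
      m <- mean(x)
      s <- stats::sd(x)
      means[cond] <- m
      if (!(m > 0) || !is.finite(100 * s / m) || 100 * s / m >= cv_max) {
        ok <- FALSE
      }
    }
    if (ok) {
      ratio <- means["treated"] / means["control"]
      cls <- if (ratio < dropout_max) "dropout"
             else if (ratio > retained_min) "retained" else "neutral"
    }
    out[id] <- cls
  }
  out
}

# shared fixture: a small deterministic signal matrix
toy_signals <- function() {
  expand_df <- expand.grid(
    mirna_id = c("mA", "mB", "mC"),
    array_id = 1:2,
    condition = c("control", "treated"),
    stringsAsFactors = FALSE
  )
  expand_df$signal <- c(
    100, 1000, 10, 110, 900, 12,    # control arrays 1, 2
    10, 9000, 11, 12, 11000, 10     # treated arrays 1, 2
  )
  expand_df
}
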