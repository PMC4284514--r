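# k-of-n consensus over target-prediction gene lists and canonical miRNA
# seed-site scanning of 3'-UTR / reporter sequences.

#' A named set of predicted target genes
#'
#' Normalizes a predictor's gene list: symbols are whitespace-stripped,
#' uppercased and de-duplicated. Matching across predictors is exact
#' case-insensitive string equality (no alias or ortholog mapping).
#'
#' @param predictor_name Label of the prediction algorithm.
#' @param genes Character vector of gene symbols.
#' @return An object of class `prediction_set` with elements
#'   `predictor_name` and `genes` (sorted unique symbols).
#' @examples
#' prediction_set("toy", c(" cltc", "EP300", "CLTC"))
#' @export
prediction_set <- function(predictor_name, genes) {
  g <- toupper(trimws(as.character(genes)))
  g <- sort(unique(g[nzchar(g)]))
  structure(list(predictor_name = predictor_name, genes = g),
            class = "prediction_set")
}

as_gene_sets <- function(sets) {
  if (inherits(sets, "prediction_set")) sets <- list(sets)
  lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "prediction_set")) return(s)
    nm <- names(sets)[i]
    prediction_set(if (!is.null(nm) && nzchar(nm)) nm else paste0("set", i), s)
  })
}

#' k-of-n consensus over prediction sets
#'
#' Counts, for every gene in the union of the prediction sets, how many
#' sets contain it, and returns the genes supported by at least `k`
#' predictors. `consensus(sets, 1)` is the union; `consensus(sets,
#' length(sets))` is the intersection.
#'
#' @param sets List of [prediction_set()] objects (or plain character
#'   vectors, which are normalized the same way).
#' @param k Minimum number of supporting predictors, `1 <= k <= length(sets)`.
#' @return An object of class `consensus_result`: list with `support`
#'   (named integer vector over the union), `k`, `n_sets`, and
#'   `consensus_genes` (sorted).
#' @examples
#' consensus(list(a = c("A", "B"), b = c("A", "C"), c = "A", d = "D"), k = 3)
#' @export
consensus <- function(sets, k) {
  sets <- as_gene_sets(sets)
  if (length(sets) == 0) stop("`sets` must be nonempty")
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > length(sets)) {
    stop("`k` must lie in [1, ", length(sets), "]")
  }
  all_genes <- unlist(lapply(sets, `[[`, "genes"), use.names = FALSE)
  support <- table(all_genes)
  support <- stats::setNames(as.integer(support), names(support))
  support <- support[order(names(support))]
  structure(
    list(support = support, k = as.integer(k), n_sets = length(sets),
         consensus_genes = sort(names(support)[support >= k])),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus: %d of %d genes supported by >= %d of %d sets\n",
              length(x$consensus_genes), length(x$support), x$k, x$n_sets))
  if (length(x$consensus_genes)) {
    cat(" ", paste(x$consensus_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exclusive Venn region counts for 2-4 prediction sets
#'
#' Counts the genes falling in every exclusive region of the Venn diagram
#' of the sets (e.g. "in sets 1 and 3 but not 2 and 4"). Region counts sum
#' to the size of the union.
#'
#' @param sets List of 2 to 4 [prediction_set()] objects or character
#'   vectors.
#' @return Named integer vector over all `2^n - 1` exclusive regions; names
#'   join the member predictor names with `"&"`.
#' @examples
#' venn_counts(list(x = c("A", "B"), y = c("B", "C")))
#' @export
venn_counts <- function(sets) {
  sets <- as_gene_sets(sets)
  n <- length(sets)
  if (n < 2 || n > 4) stop("`venn_counts` supports 2 to 4 sets")
  nms <- vapply(sets, `[[`, "", "predictor_name")
  union_genes <- sort(unique(unlist(lapply(sets, `[[`, "genes"))))
  membership <- vapply(sets, function(s) union_genes %in% s$genes,
                       logical(length(union_genes)))
  membership <- matrix(membership, nrow = length(union_genes))
  # all nonempty predictor subsets, ordered by size then position
  subsets <- unlist(lapply(seq_len(n), function(sz) {
    utils::combn(n, sz, simplify = FALSE)
  }), recursive = FALSE)
  counts <- vapply(subsets, function(idx) {
    inside <- rowSums(membership[, idx, drop = FALSE]) == length(idx)
    outside <- rowSums(membership[, -idx, drop = FALSE]) == 0
    sum(inside & (if (length(idx) == n) TRUE else outside))
  }, integer(1))
  names(counts) <- vapply(subsets, function(idx) {
    paste(nms[idx], collapse = "&")
  }, "")
  counts
}

COMPLEMENT_DNA <- c(A = "T", C = "G", G = "C", T = "A")

normalize_nt <- function(seq, what = "sequence") {
  s <- toupper(chartr("u", "U", seq))
  s <- chartr("U", "T", s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(COMPLEMENT_DNA))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d of %s",
                 chars[bad[1]], bad[1], what))
  }
  s
}

#' Reverse complement of a nucleotide sequence
#'
#' Watson-Crick reverse complement with U/T treated as equivalent on input;
#' `output_alphabet` selects whether the result is written as DNA or RNA.
#' An involution up to U/T normalization: `reverse_complement(
#' reverse_complement(x))` recovers `x`.
#'
#' @param seq Nucleotide string over A/C/G/T/U (case-insensitive).
#' @param output_alphabet `"DNA"` (default) or `"RNA"`.
#' @return Reverse-complemented string.
#' @examples
#' reverse_complement("TGAGCGT", "RNA")  # "ACGCUCA"
#' @export
reverse_complement <- function(seq, output_alphabet = c("DNA", "RNA")) {
  output_alphabet <- match.arg(output_alphabet)
  if (!is.character(seq) || length(seq) != 1) {
    stop("`seq` must be a single string")
  }
  if (!nzchar(seq)) return("")
  s <- normalize_nt(seq)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))
  )
  if (output_alphabet == "RNA") chartr("T", "U", rc) else rc
}

#' Scan a target sequence for canonical miRNA seed sites
#'
#' Enumerates canonical seed-match sites of the miRNA on the given (sense)
#' strand of the target, using the standard site nomenclature. Writing
#' `rc()` for reverse complement and numbering miRNA nucleotides 5' to 3':
#'
#' * `6mer` — target matches `rc(miRNA 2-7)`;
#' * `7mer-m8` — target matches `rc(miRNA 2-8)`;
#' * `7mer-A1` — `rc(miRNA 2-7)` followed by an `A` in the target (the
#'   position opposite miRNA nucleotide 1);
#' * `8mer-A1` — `rc(miRNA 2-8)` followed by an `A`.
#'
#' Each matched locus is reported once, as its most specific type (an
#' 8mer-A1 suppresses the 7mer-m8, 7mer-A1 and 6mer it contains, and so
#' on). Coordinates are 1-based inclusive on the target. Alongside the
#' site span, each record carries the *exact seed match* — the substring
#' Watson-Crick complementary to the seed region — and its length (7 when
#' miRNA position 8 is matched, else 6); the `A1` adduct is an unpaired
#' anchor and does not extend the exact seed match.
#'
#' @param mirna Mature miRNA sequence, 5' to 3', RNA or DNA alphabet,
#'   length >= 8.
#' @param target Target sequence (3'-UTR or reporter insert), sense strand,
#'   length >= 6.
#' @return Data frame with columns `site_type`, `start`, `end`,
#'   `site_sequence`, `seed_match`, `seed_match_length`; zero rows when no
#'   site is present.
#' @examples
#' seed_sites("CACGCUCAUGCACACACCCACA", "AAATGAGCGTCCC")
#' @export
seed_sites <- function(mirna, target) {
  if (inherits(mirna, "mature_mirna")) mirna <- mirna$sequence
  m <- normalize_nt(mirna, "miRNA")
  if (nchar(m) < 8) stop("miRNA must be at least 8 nt long")
  t_seq <- normalize_nt(target, "target")
  if (nchar(t_seq) < 6) stop("target must be at least 6 nt long")

  seed6 <- reverse_complement(substr(m, 2, 7))   # core match, miRNA 2-7
  comp8 <- COMPLEMENT_DNA[[substr(m, 8, 8)]]     # target base opposite nt 8
  tlen <- nchar(t_seq)

  # all core 6mer match positions
  starts <- integer(0)
  from <- 1L
  repeat {
    p <- regexpr(seed6, substr(t_seq, from, tlen), fixed = TRUE)
    if (p < 0) break
    starts <- c(starts, from + as.integer(p) - 1L)
    from <- from + as.integer(p)
    if (from > tlen - 5L) break
  }
  if (!length(starts)) {
    return(data.frame(site_type = character(0), start = integer(0),
                      end = integer(0), site_sequence = character(0),
                      seed_match = character(0),
                      seed_match_length = integer(0),
                      stringsAsFactors = FALSE))
  }

  rows <- lapply(starts, function(p) {
    has_m8 <- p > 1L && substr(t_seq, p - 1L, p - 1L) == comp8
    has_a1 <- p + 6L <= tlen && substr(t_seq, p + 6L, p + 6L) == "A"
    if (has_m8 && has_a1) {
      st <- p - 1L; en <- p + 6L; type <- "8mer-A1"
    } else if (has_m8) {
      st <- p - 1L; en <- p + 5L; type <- "7mer-m8"
    } else if (has_a1) {
      st <- p; en <- p + 6L; type <- "7mer-A1"
    } else {
      st <- p; en <- p + 5L; type <- "6mer"
    }
    seed_match <- if (has_m8) substr(t_seq, p - 1L, p + 5L)
                  else substr(t_seq, p, p + 5L)
    data.frame(site_type = type, start = st, end = en,
               site_sequence = substr(t_seq, st, en),
               seed_match = seed_match,
               seed_match_length = nchar(seed_match),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
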