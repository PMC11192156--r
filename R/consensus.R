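# Replicate-scan consensus: each batch of seeds is scanned twice (the seeds
# are rearranged/flipped between passes), every seed is classified on both
# scans, and the two per-species count vectors are reconciled into a
# consensus with a discrepancy measure. Seeds are not individually matched
# across scans, so the discrepancy is defined on count vectors: half the L1
# distance counts seeds that changed class, and half the total difference
# counts seeds present in only one scan.

#' Pair replicate scans into batches
#'
#' Groups scan metadata by batch (site + trap + date + fill status) and
#' pairs replicate 1 with replicate 2. Batches with a single scan are
#' passed through flagged as unpaired.
#'
#' @param metadata `data.frame` from [parse_tags()].
#' @return `data.frame` with one row per batch: `batch_id`, `tag_rep1`,
#'   `tag_rep2` (`NA` when unpaired), and `paired`.
#' @export
pair_replicates <- function(metadata) {
  if (anyNA(metadata$replicate_index))
    stop("replicate indices are required to pair scans")
  out <- lapply(split(metadata, metadata$batch_id), function(g) {
    if (nrow(g) > 2L || any(duplicated(g$replicate_index)) ||
        any(g$replicate_index > 2L))
      stop("batch ", g$batch_id[1], " has more than two replicate scans; ",
           "only duplicate scans are supported")
    r1 <- g$source_tag[g$replicate_index == 1L]
    r2 <- g$source_tag[g$replicate_index == 2L]
    data.frame(batch_id = g$batch_id[1],
               tag_rep1 = if (length(r1)) r1 else NA_character_,
               tag_rep2 = if (length(r2)) r2 else NA_character_,
               paired = length(r1) == 1L && length(r2) == 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-species seed counts
#'
#' @param calls Vector of per-seed species labels (may be empty).
#' @param class_labels Species vocabulary; counts cover the full vocabulary,
#'   zeros included.
#' @return Named integer vector over `class_labels`.
#' @export
species_counts <- function(calls, class_labels) {
  bad <- setdiff(unique(calls), class_labels)
  if (length(bad) > 0L)
    stop("label(s) outside the vocabulary: ", paste(bad, collapse = ", "))
  tab <- table(factor(calls, levels = class_labels))
  setNames(as.integer(tab), class_labels)
}

# Largest-remainder apportionment of per-species means to integers summing
# to the half-up-rounded mean total.
apportion_counts <- function(means, total) {
  base <- floor(means)
  rem <- means - base
  short <- as.integer(round(total - sum(base)))
  if (short > 0L) {
    ord <- order(-rem, seq_along(means))  # ties -> species order
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Consensus counts and between-scan discrepancy
#'
#' The consensus is the elementwise mean of the two replicate count vectors
#' (an integer variant rounds half-up and preserves the rounded mean total
#' by largest-remainder apportionment). The absolute discrepancy is
#' `0.5 * sum(|c1 - c2|) + 0.5 * |total1 - total2|`: seeds that changed
#' class between scans plus seeds detected in only one scan. The relative
#' discrepancy standardizes by the mean number of seeds per scan.
#'
#' @param c1,c2 Named per-species count vectors over the same vocabulary
#'   (see [species_counts()]).
#' @return List with `consensus` (numeric, possibly half-integer),
#'   `consensus_int`, `discrepancy_abs`, `discrepancy_rel`, and the two
#'   totals.
#' @examples
#' a <- c(ABAM = 3, TSHE = 2); b <- c(ABAM = 2, TSHE = 3)
#' consensus_and_discrepancy(a, b)$discrepancy_abs  # 1 seed changed class
#' @export
consensus_and_discrepancy <- function(c1, c2) {
  if (is.null(names(c1)) || !identical(names(c1), names(c2)))
    stop("count vectors must share one species vocabulary, in the same order")
  t1 <- sum(c1); t2 <- sum(c2)
  cons <- (c1 + c2) / 2
  total_int <- floor(sum(cons) + 0.5)
  disc_abs <- 0.5 * sum(abs(c1 - c2)) + 0.5 * abs(t1 - t2)
  disc_rel <- if (t1 + t2 == 0) 0 else disc_abs / ((t1 + t2) / 2)
  list(consensus = cons,
       consensus_int = setNames(apportion_counts(cons, total_int), names(cons)),
       discrepancy_abs = disc_abs, discrepancy_rel = disc_rel,
       total_rep1 = t1, total_rep2 = t2)
}

#' Consensus report for classified scans
#'
#' Runs [pair_replicates()] over the metadata of a calls table and computes
#' per-batch consensus counts and discrepancies from the predicted labels.
#'
#' @param calls `data.frame` with columns `tag` and `species` (one row per
#'   classified seed).
#' @param class_labels Species vocabulary.
#' @param metadata Optional pre-parsed metadata; defaults to parsing the
#'   tags in `calls`.
#' @return List with `per_batch` (list of per-batch
#'   [consensus_and_discrepancy()] results, named by batch) and `table`
#'   (long `data.frame`: batch, species, rep1/rep2/consensus counts,
#'   discrepancies).
#' @export
consensus_report <- function(calls, class_labels, metadata = NULL) {
  if (is.null(metadata)) metadata <- parse_tags(unique(calls$tag))
  pairs <- pair_replicates(metadata)
  per_batch <- list()
  rows <- list()
  for (i in seq_len(nrow(pairs))) {
    if (!pairs$paired[i]) next
    k1 <- species_counts(calls$species[calls$tag == pairs$tag_rep1[i]], class_labels)
    k2 <- species_counts(calls$species[calls$tag == pairs$tag_rep2[i]], class_labels)
    cd <- consensus_and_discrepancy(k1, k2)
    per_batch[[pairs$batch_id[i]]] <- cd
    rows[[i]] <- data.frame(batch_id = pairs$batch_id[i], species = class_labels,
                            count_rep1 = as.integer(k1), count_rep2 = as.integer(k2),
                            consensus = as.numeric(cd$consensus),
                            consensus_int = cd$consensus_int,
                            discrepancy_abs = cd$discrepancy_abs,
                            discrepancy_rel = cd$discrepancy_rel,
                            stringsAsFactors = FALSE)
  }
  list(per_batch = per_batch,
       table = if (length(rows)) do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
               else data.frame(),
       unpaired = pairs$batch_id[!pairs$paired])
}
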