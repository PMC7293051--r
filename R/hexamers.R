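# 3' UTR hexamer statistics: enrichment of 6-mers in a foreground sequence
# set versus background, and per-hexamer conservation rates from a per-base
# conservation mask. Occurrences are counted at every position (overlapping
# windows), the standard k-mer convention, so a sequence of length L with no
# ambiguous bases contributes exactly L - 5 window counts.

ALPHABET <- c("A", "C", "G", "T")

as_seq_vector <- function(x, arg) {
  if (inherits(x, "DNAStringSet")) {
    s <- as.character(x)
  } else if (is.data.frame(x)) {
    stopifnot(all(c("entity_id", "seq") %in% names(x)))
    s <- setNames(as.character(x$seq), x$entity_id)
  } else if (is.character(x)) {
    s <- x
  } else {
    stop_cosedim(sprintf("`%s` must be sequences (character, tibble, or DNAStringSet).", arg),
                 "cosedim_validation_error")
  }
  s <- toupper(s)
  if (length(s) == 0L) {
    stop_cosedim(sprintf("`%s` is empty.", arg), "cosedim_empty_error")
  }
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    stop_cosedim(sprintf("`%s` contains characters outside ACGTN.", arg),
                 "cosedim_validation_error")
  }
  s
}

# Overlapping 6-mer counts summed over a sequence set; windows containing N
# are skipped. Biostrings does the counting.
count_hexamers <- function(seqs) {
  dss <- Biostrings::DNAStringSet(seqs)
  counts <- Biostrings::oligonucleotideFrequency(dss, width = 6L)
  colSums(counts)
}

#' Hexamer enrichment between foreground and background UTR sets
#'
#' Counts every overlapping 6-mer occurrence in the two sequence sets and
#' scores each of the 4096 hexamers by the log2 ratio of its
#' pseudocount-smoothed, total-normalized frequencies:
#' `log2((fg + pc) / (fg_total + 4096 pc)) - log2((bg + pc) / (bg_total + 4096 pc))`.
#' Normalizing by totals means a difference in overall sequence content
#' between the sets cannot masquerade as motif enrichment.
#'
#' @param fg_utrs,bg_utrs Foreground and background sequences: character
#'   vector, tibble with `entity_id`/`seq`, or `DNAStringSet`. Sequences are
#'   over ACGTN; windows containing N are skipped.
#' @param pseudocount Smoothing pseudocount, default 1.
#' @return A `hexamer_stats` tibble sorted by decreasing `log2_ratio`:
#'   `hexamer`, `fg_count`, `bg_count`, `log2_ratio`.
#' @export
hexamer_enrichment <- function(fg_utrs, bg_utrs, pseudocount = 1) {
  assert_scalar_number(pseudocount, "pseudocount", min = 0)
  fg <- count_hexamers(as_seq_vector(fg_utrs, "fg_utrs"))
  bg <- count_hexamers(as_seq_vector(bg_utrs, "bg_utrs"))
  pc <- pseudocount
  lr <- log2((fg + pc) / (sum(fg) + 4096 * pc)) -
    log2((bg + pc) / (sum(bg) + 4096 * pc))
  out <- tibble(hexamer = names(fg), fg_count = as.integer(fg),
                bg_count = as.integer(bg), log2_ratio = lr) |>
    arrange(desc(.data$log2_ratio), .data$hexamer)
  class(out) <- c("hexamer_stats", class(out))
  out
}

#' Per-hexamer conservation rate from per-base masks
#'
#' For each hexamer, the fraction of its occurrences whose six positions are
#' all marked conserved in a per-base boolean mask (e.g. full conservation in
#' a multi-species alignment). The rate is only defined for hexamers with at
#' least one occurrence.
#'
#' @param utrs Sequences (see [hexamer_enrichment()] for accepted forms).
#' @param masks List of logical vectors, one per sequence and of equal length
#'   (named by sequence id when `utrs` carries names/ids).
#' @return Tibble `hexamer`, `n_instances`, `n_conserved`, `conservation_rate`
#'   for hexamers occurring at least once.
#' @export
hexamer_conservation_rate <- function(utrs, masks) {
  seqs <- as_seq_vector(utrs, "utrs")
  if (length(masks) != length(seqs)) {
    stop_cosedim("`masks` must have one entry per sequence.", "cosedim_validation_error")
  }
  if (!is.null(names(seqs)) && !is.null(names(masks))) {
    masks <- masks[names(seqs)]
  }
  tallies <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    mask <- as.logical(masks[[i]])
    if (length(mask) != nchar(s)) {
      stop_cosedim(sprintf("Mask length %d != sequence length %d for record %s.",
                           length(mask), nchar(s),
                           names(seqs)[i] %||% as.character(i)),
                   "cosedim_validation_error")
    }
    L <- nchar(s)
    if (L < 6L) next
    starts <- seq_len(L - 5L)
    kmers <- substring(s, starts, starts + 5L)
    valid <- !grepl("N", kmers, fixed = TRUE)
    if (!any(valid)) next
    # window fully conserved iff the 6-base rolling sum of the mask is 6
    cs <- cumsum(c(0L, as.integer(mask)))
    conserved <- (cs[starts + 6L] - cs[starts]) == 6L
    tallies[[i]] <- tibble(hexamer = kmers[valid], conserved = conserved[valid])
  }
  all_t <- bind_rows(tallies)
  if (!nrow(all_t)) {
    stop_cosedim("No countable hexamer instances.", "cosedim_empty_error")
  }
  all_t |>
    group_by(.data$hexamer) |>
    summarise(n_instances = n(), n_conserved = sum(.data$conserved),
              .groups = "drop") |>
    mutate(conservation_rate = .data$n_conserved / .data$n_instances) |>
    arrange(.data$hexamer)
}

#' Read sequences from FASTA
#' @param path FASTA file path.
#' @return Tibble `entity_id`, `seq`.
#' @export
read_utr_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  tibble(entity_id = names(dss), seq = unname(as.character(dss)))
}

#' Write sequences to FASTA
#' @param utrs Tibble `entity_id`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  utrs <- as_tibble(utrs)
  dss <- Biostrings::DNAStringSet(setNames(utrs$seq, utrs$entity_id))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read per-base conservation masks from an interval track
#'
#' The track is a TSV with columns `entity_id`, `length`, `conserved`, where
#' `conserved` lists 0-based half-open conserved intervals as
#' `start-end` pairs separated by `;` (empty for none).
#'
#' @param path Track file path.
#' @return Named list of logical vectors.
#' @export
read_conservation_track <- function(path) {
  tr <- readr::read_tsv(path, comment = "#", col_types = "cic", progress = FALSE)
  masks <- lapply(seq_len(nrow(tr)), function(i) {
    mask <- rep(FALSE, tr$length[i])
    spec <- tr$conserved[i]
    if (!is.na(spec) && nzchar(spec)) {
      for (iv in strsplit(spec, ";", fixed = TRUE)[[1L]]) {
        se <- as.integer(strsplit(iv, "-", fixed = TRUE)[[1L]])
        if (length(se) != 2L || anyNA(se) || se[1L] < 0 || se[2L] > tr$length[i] ||
            se[1L] >= se[2L]) {
          stop_cosedim(sprintf("Bad interval '%s' for record %s.", iv, tr$entity_id[i]),
                       "cosedim_parse_error")
        }
        mask[(se[1L] + 1L):se[2L]] <- TRUE
      }
    }
    mask
  })
  setNames(masks, tr$entity_id)
}

#' Write per-base conservation masks as an interval track
#' @param masks Named list of logical vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_track <- function(masks, path) {
  rows <- vapply(names(masks), function(nm) {
    mask <- masks[[nm]]
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    iv <- paste0(starts[r$values], "-", ends[r$values], collapse = ";")
    paste(nm, length(mask), iv, sep = "\t")
  }, "")
  writeLines(c("entity_id\tlength\tconserved", rows), path)
  invisible(path)
}
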