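#' Demultiplex pooled read pairs by internal dual indexes
#'
#' Assigns each read pair to a well when the first 8 nt of R1 and R2 match
#' the well's index pair (honouring orientation: reversed wells match with
#' roles swapped), each within `max_mismatch` substitutions. Matching is
#' substitution-only and anchored at position 0. Pairs tying across two or
#' more wells at the minimal total mismatch are reported ambiguous, never
#' rescued. Assigned reads have index, declared spacer and priming sequence
#' removed from the 5' end.
#'
#' @param r1,r2 synchronized mates: FASTQ paths or named character vectors.
#' @param plate a `primer_plate`.
#' @param max_mismatch allowed substitutions per index (0-2).
#' @param primer_search when TRUE, spacer drift is absorbed by locating the
#'   priming sequence (allowing 1 mismatch) instead of trusting the
#'   declared spacer length.
#' @return List with `wells` (per-well list of trimmed `r1`/`r2` vectors),
#'   `assignment` (read_id/well_id/status/mismatches), and `report`
#'   (per-well counts and mean index mismatches, plus `unassigned`,
#'   `ambiguous`, `total`).
#' @export
demultiplex <- function(r1, r2, plate, max_mismatch = 1L,
                        primer_search = FALSE) {
  assert_plate(plate)
  if (max_mismatch < 0L || max_mismatch > 2L) {
    stop("max_mismatch must be between 0 and 2", call. = FALSE)
  }
  if (is.character(r1) && length(r1) == 1L && file.exists(r1)) {
    r1 <- read_fastq(r1)
  }
  if (is.character(r2) && length(r2) == 1L && file.exists(r2)) {
    r2 <- read_fastq(r2)
  }
  if (length(r1) != length(r2)) {
    stop("R1/R2 record counts differ (", length(r1), " vs ", length(r2), ")",
         call. = FALSE)
  }
  id1 <- sub("/[12]$", "", names(r1))
  id2 <- sub("/[12]$", "", names(r2))
  bad <- which(id1 != id2)
  if (length(bad)) {
    stop(sprintf("desynchronized FASTQ at record %d: '%s' vs '%s'",
                 bad[1L], id1[bad[1L]], id2[bad[1L]]), call. = FALSE)
  }
  n <- length(r1)
  nw <- nrow(plate)
  # expected R1-side/R2-side index per well, honouring orientation
  rev_well <- plate$orientation == "reversed"
  exp1 <- ifelse(rev_well, plate$index_r, plate$index_f)
  exp2 <- ifelse(rev_well, plate$index_f, plate$index_r)

  well <- rep(NA_integer_, n)
  mmtot <- rep(NA_integer_, n)
  status <- rep("unassigned", n)
  if (n > 0L) {
    i1 <- substr(r1, 1L, 8L)
    i2 <- substr(r2, 1L, 8L)
    key <- paste(i1, i2)
    exact <- match(key, paste(exp1, exp2))
    hit <- !is.na(exact)
    well[hit] <- exact[hit]
    mmtot[hit] <- 0L
    status[hit] <- "assigned"
    rest <- which(!hit)
    if (length(rest) && max_mismatch > 0L) {
      c1 <- seq_char_matrix(i1[rest])
      c2 <- seq_char_matrix(i2[rest])
      best <- rep(Inf, length(rest))
      bestw <- rep(NA_integer_, length(rest))
      ties <- rep(0L, length(rest))
      for (w in seq_len(nw)) {
        a <- matrix(strsplit(exp1[w], "")[[1L]], length(rest), 8L, byrow = TRUE)
        b <- matrix(strsplit(exp2[w], "")[[1L]], length(rest), 8L, byrow = TRUE)
        mm1 <- rowSums(c1 != a)
        mm2 <- rowSums(c2 != b)
        tot <- ifelse(mm1 <= max_mismatch & mm2 <= max_mismatch,
                      mm1 + mm2, Inf)
        better <- tot < best
        equal <- is.finite(tot) & tot == best
        best[better] <- tot[better]
        bestw[better] <- w
        ties[better] <- 1L
        ties[equal] <- ties[equal] + 1L
      }
      ok <- is.finite(best) & ties == 1L
      amb <- is.finite(best) & ties > 1L
      well[rest[ok]] <- bestw[ok]
      mmtot[rest[ok]] <- as.integer(best[ok])
      status[rest[ok]] <- "assigned"
      status[rest[amb]] <- "ambiguous"
    }
  }

  plen1 <- nchar(ifelse(rev_well, plate$prime_r, plate$prime_f))
  plen2 <- nchar(ifelse(rev_well, plate$prime_f, plate$prime_r))
  sp1 <- ifelse(rev_well, plate$spacer_r, plate$spacer_f)
  sp2 <- ifelse(rev_well, plate$spacer_f, plate$spacer_r)
  prime1 <- ifelse(rev_well, plate$prime_r, plate$prime_f)
  prime2 <- ifelse(rev_well, plate$prime_f, plate$prime_r)

  locate_cut <- function(reads, declared, prime) {
    # spacer-drift fallback: scan offsets 8..13 for the priming sequence
    plen <- nchar(prime)
    pchars <- strsplit(prime, "")[[1L]]
    cut <- rep(8L + declared + plen, length(reads))
    if (!primer_search) return(cut)
    for (k in seq_along(reads)) {
      for (off in 8:13) {
        seg <- substr(reads[k], off + 1L, off + plen)
        if (nchar(seg) == plen &&
              sum(strsplit(seg, "")[[1L]] != pchars) <= 1L) {
          cut[k] <- off + plen
          break
        }
      }
    }
    cut
  }

  wells_out <- stats::setNames(vector("list", nw), plate$well_id)
  per_well_n <- integer(nw)
  per_well_mm <- rep(NA_real_, nw)
  for (w in seq_len(nw)) {
    sel <- which(!is.na(well) & well == w)
    per_well_n[w] <- length(sel)
    if (length(sel)) {
      per_well_mm[w] <- mean(mmtot[sel])
      cut1 <- locate_cut(r1[sel], sp1[w], prime1[w])
      cut2 <- locate_cut(r2[sel], sp2[w], prime2[w])
      wells_out[[w]] <- list(
        r1 = stats::setNames(substr(r1[sel], cut1 + 1L, nchar(r1[sel])),
                             id1[sel]),
        r2 = stats::setNames(substr(r2[sel], cut2 + 1L, nchar(r2[sel])),
                             id2[sel])
      )
    } else {
      wells_out[[w]] <- list(r1 = character(0), r2 = character(0))
    }
  }
  n_amb <- sum(status == "ambiguous")
  n_un <- sum(status == "unassigned")
  stopifnot(sum(per_well_n) + n_amb + n_un == n)
  list(
    wells = wells_out,
    assignment = data.frame(read_id = if (n) id1 else character(0),
                            well_id = plate$well_id[well],
                            status = status,
                            mismatches = mmtot,
                            stringsAsFactors = FALSE),
    report = list(
      per_well = data.frame(well_id = plate$well_id,
                            n_assigned = per_well_n,
                            mean_index_mismatches = per_well_mm,
                            stringsAsFactors = FALSE),
      unassigned = n_un, ambiguous = n_amb, total = n
    )
  )
}

#' Trim fixed lengths from both read ends
#'
#' Applied after index/spacer/primer removal to drop residual adapter
#' bases (10 nt from each end in the standard pipeline). Reads shorter than
#' `n5 + n3 + 1` are dropped and counted in the `n_dropped` attribute.
#'
#' @param reads named character vector.
#' @param n5,n3 bases to remove from the 5' and 3' ends.
#' @return Trimmed named character vector with attribute `n_dropped`.
#' @export
trim_insert_ends <- function(reads, n5 = 10L, n3 = 10L) {
  if (n5 < 0L || n3 < 0L) stop("n5 and n3 must be >= 0", call. = FALSE)
  len <- nchar(reads)
  keep <- len >= (n5 + n3 + 1L)
  out <- substr(reads[keep], n5 + 1L, len[keep] - n3)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
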