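#' Align a consensus read to its amplicon reference
#'
#' Semi-global alignment (free end gaps, match +1, mismatch -1, gap
#' open -2, gap extend -1; a length-L gap costs open + ext*(L-1))
#' of the consensus insert against the amplicon, with indel events
#' left-normalized afterwards so variant identity is an exact tuple.
#' `N` positions never produce mismatch events and are excluded from
#' coverage at that position. Same-length sequences with few
#' differences take a positional fast path (substitutions only); the
#' dynamic program runs otherwise.
#'
#' @param consensus consensus sequence (may contain `N`).
#' @param x the [assay()] aligned against.
#' @param min_identity alignments below this identity (matches over
#'   aligned non-N columns) are discarded as unalignable (default 0.7).
#' @param max_fast_mismatch same-length fast path allowance
#'   (default 3).
#' @return list with `events` (data.table `pos`, `ref`, `alt`,
#'   `vclass`; 0-based left-normalized), `covered` (0-based half-open
#'   reference interval spanned), `n_pos` (0-based reference positions
#'   masked by `N`), `identity`; or `NULL` when the consensus is
#'   unalignable (identity below `min_identity` or only a short
#'   spurious overlap).
#' @export
align_consensus <- function(consensus, x, min_identity = 0.7,
                            max_fast_mismatch = 3L) {
  ref <- x$amplicon_seq
  if (consensus == ref) {
    return(list(events = empty_events(), covered = c(0L, nchar(ref)),
                n_pos = integer(0), identity = 1))
  }
  if (nchar(consensus) == nchar(ref)) {
    qs <- strsplit(consensus, "")[[1]]
    rs <- strsplit(ref, "")[[1]]
    isn <- qs == "N"
    diffpos <- which(qs != rs & !isn)
    if (length(diffpos) <= max_fast_mismatch) {
      idn <- sum(qs == rs & !isn) / max(1L, sum(!isn))
      if (idn < min_identity)
        return(NULL)
      ev <- if (length(diffpos)) data.table::data.table(
        pos = diffpos - 1L, ref = rs[diffpos], alt = qs[diffpos],
        vclass = "SNV") else empty_events()
      return(list(events = ev, covered = c(0L, nchar(ref)),
                  n_pos = which(isn) - 1L, identity = idn))
    }
  }
  a <- cpp_align(consensus, ref)
  extract_events(a$query, a$ref, x, min_identity)
}

empty_events <- function() {
  data.table::data.table(pos = integer(0), ref = character(0),
                         alt = character(0), vclass = character(0))
}

# Turn a gapped alignment (query over reference) into left-normalized
# events. End-gap columns are soft: a query gap at either end means the
# reference is uncovered there (no deletion event); a reference gap at
# either end is an unaligned query overhang (no insertion event).
extract_events <- function(qa, ra, x, min_identity = 0.7) {
  q <- strsplit(qa, "")[[1]]
  r <- strsplit(ra, "")[[1]]
  nc <- length(q)
  inner <- which(q != "-" & r != "-")
  if (!length(inner)) return(NULL)
  first <- inner[1L]; last <- inner[length(inner)]
  # covered reference interval
  rpos <- cumsum(r != "-")            # 1-based ref position per column
  cov_start <- rpos[first] - 1L       # 0-based
  cov_end <- rpos[last]               # half-open
  events <- list()
  npos <- integer(0)
  matches <- 0L; aligned <- 0L
  i <- first
  while (i <= last) {
    if (q[i] != "-" && r[i] != "-") {
      if (q[i] == "N") {
        npos <- c(npos, rpos[i] - 1L)
      } else {
        aligned <- aligned + 1L
        if (q[i] == r[i]) {
          matches <- matches + 1L
        } else {
          events[[length(events) + 1L]] <-
            list(pos = rpos[i] - 1L, ref = r[i], alt = q[i],
                 vclass = "SNV")
        }
      }
      i <- i + 1L
    } else if (q[i] == "-") {          # deletion run
      j <- i
      while (j <= last && q[j] == "-") j <- j + 1L
      dref <- paste(r[i:(j - 1L)], collapse = "")
      nv <- left_normalize(rpos[i] - 1L, dref, "", x$amplicon_seq)
      events[[length(events) + 1L]] <-
        list(pos = nv$pos, ref = nv$ref, alt = "", vclass = "DEL")
      i <- j
    } else {                           # insertion run (gap in ref)
      j <- i
      while (j <= last && r[j] == "-") j <- j + 1L
      ains <- paste(q[i:(j - 1L)], collapse = "")
      ains <- gsub("N", "", ains)
      if (nchar(ains)) {
        nv <- left_normalize(rpos[i], "", ains, x$amplicon_seq)
        events[[length(events) + 1L]] <-
          list(pos = nv$pos, ref = "", alt = nv$alt, vclass = "INS")
      }
      i <- j
    }
  }
  idn <- if (aligned > 0L) matches / aligned else 0
  # free end gaps allow short spurious overlaps: require at least half
  # of the shorter sequence to be aligned as well as the identity bound
  qlen <- sum(q != "-")
  rlen <- length(r) - sum(r == "-")
  if (aligned < 0.5 * min(qlen, rlen) || idn < min_identity)
    return(NULL)
  ev <- if (length(events)) data.table::rbindlist(events) else empty_events()
  list(events = ev, covered = c(cov_start, cov_end), n_pos = npos,
       identity = idn)
}

#' Build a per-assay pileup from consensus reads
#'
#' Aligns every consensus read of one assay to the amplicon reference
#' and aggregates events and coverage. Consensus reads matching the
#' assay's canonical spike-in insertion are routed out of the pileup
#' (counted in `n_spikein`, never contributing to variant calls);
#' unalignable consensus reads are counted and discarded. Unique
#' consensus sequences are aligned once and weighted by multiplicity.
#'
#' @param consensus_dt rows of [build_consensus_set()] for one assay
#'   (columns `consensus`, `family_size`), or a character vector of
#'   consensus sequences.
#' @param x the [assay()].
#' @param spikein logical: detect and route spike-in consensus reads
#'   (default `TRUE`).
#' @return object of class `umivar_pileup`: list with `assay_id`,
#'   `length`, `coverage` (integer vector, consensus reads covering
#'   each 0-based position, `N`-masked excluded), `events` (data.table
#'   `pos`, `ref`, `alt`, `vclass`, `count`), `n_consensus`,
#'   `n_spikein`, `n_unalignable`.
#' @export
build_pileup <- function(consensus_dt, x, spikein = TRUE) {
  seqs <- if (is.character(consensus_dt)) consensus_dt
          else consensus_dt$consensus
  L <- nchar(x$amplicon_seq)
  cov <- integer(L)
  evl <- list()
  n_spike <- 0L
  n_unaln <- 0L
  n_cons <- 0L
  spk <- if (spikein) spikein_event(x) else NULL
  tab <- table(seqs)
  for (k in seq_along(tab)) {
    s <- names(tab)[k]
    w <- as.integer(tab[[k]])
    al <- align_consensus(s, x)
    if (is.null(al)) { n_unaln <- n_unaln + w; next }
    if (!is.null(spk) && nrow(al$events)) {
      is_spk <- al$events[, any(ref == "" & pos == spk$pos &
                                  alt == spk$alt)]
      if (is_spk) { n_spike <- n_spike + w; next }
    }
    n_cons <- n_cons + w
    if (al$covered[2] > al$covered[1]) {
      idx <- (al$covered[1] + 1L):al$covered[2]
      cov[idx] <- cov[idx] + w
      if (length(al$n_pos))
        cov[al$n_pos + 1L] <- cov[al$n_pos + 1L] - w
    }
    if (nrow(al$events)) {
      e <- data.table::copy(al$events)
      e[, count := w]
      evl[[length(evl) + 1L]] <- e
    }
  }
  events <- if (length(evl))
    data.table::rbindlist(evl)[, .(count = sum(count)),
                               by = .(pos, ref, alt, vclass)]
  else cbind(empty_events(), data.table::data.table(count = integer(0)))
  structure(list(assay_id = x$assay_id, length = L, coverage = cov,
                 events = events, n_consensus = n_cons,
                 n_spikein = n_spike, n_unalignable = n_unaln),
            class = "umivar_pileup")
}

#' Count spike-in consensus molecules for an assay
#'
#' Counts consensus reads whose alignment carries the assay's canonical
#' ATG insertion immediately after the forward primer. Position-specific:
#' true insertion variants elsewhere never contribute.
#'
#' @inheritParams build_pileup
#' @return integer spike-in consensus count.
#' @export
count_spikein <- function(consensus_dt, x) {
  build_pileup(consensus_dt, x, spikein = TRUE)$n_spikein
}

#' @export
print.umivar_pileup <- function(x, ...) {
  cat(sprintf("Pileup %s: %d consensus reads (%d spike-in, %d unalignable)\n",
              x$assay_id, x$n_consensus, x$n_spikein, x$n_unalignable))
  if (nrow(x$events)) print(x$events) else cat("  no events\n")
  invisible(x)
}
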