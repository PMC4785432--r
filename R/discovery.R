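#' Filter genome-mapped small-RNA reads
#'
#' Retains reads with length in \[`min_len`, `max_len`\], strictly fewer
#' than `max_mismatch` mismatches, at most `max_alignments` reported
#' alignments, and no overlap (of any length) with the known-ncRNA mask.
#'
#' @param reads BED-like data.frame: contig, start, end (0-based
#'   half-open), strand, mismatches, n_alignments.
#' @param min_len,max_len read length bounds in bases.
#' @param max_mismatch reads must have mismatches < this value.
#' @param max_alignments reads with more alignments are removed.
#' @param ncrna_mask optional data.frame (contig, start, end) of known
#'   non-coding RNA intervals.
#' @return the filtered data.frame.
#' @export
preprocess_reads <- function(reads, min_len = 17, max_len = 27,
                             max_mismatch = 2, max_alignments = 6,
                             ncrna_mask = NULL) {
  len <- reads$end - reads$start
  keep <- len >= min_len & len <= max_len &
    reads$mismatches < max_mismatch &
    reads$n_alignments <= max_alignments
  reads <- reads[keep, , drop = FALSE]
  if (!is.null(ncrna_mask) && nrow(ncrna_mask) > 0 && nrow(reads) > 0) {
    drop <- rep(FALSE, nrow(reads))
    for (ct in unique(reads$contig)) {
      mi <- ncrna_mask[ncrna_mask$contig == ct, , drop = FALSE]
      ri <- which(reads$contig == ct)
      if (nrow(mi) == 0 || length(ri) == 0) next
      ov <- IRanges::countOverlaps(
        IRanges::IRanges(reads$start[ri] + 1L, reads$end[ri]),
        IRanges::IRanges(mi$start + 1L, mi$end))
      drop[ri] <- ov > 0
    }
    reads <- reads[!drop, , drop = FALSE]
  }
  rownames(reads) <- NULL
  reads
}

#' Cluster reads into candidate ncRNA loci
#'
#' Strand-separated single-linkage clustering: reads whose intervals
#' overlap or lie within `max_gap` bases of each other merge into one
#' locus. Loci with fewer than `min_reads` reads are discarded.
#'
#' @param reads filtered read data.frame (see [preprocess_reads()]).
#' @param max_gap maximum gap in bases for merging.
#' @param min_reads minimum reads per retained locus.
#' @return list of loci, each a list(contig, start, end, strand, n_reads,
#'   reads).
#' @export
cluster_loci <- function(reads, max_gap = 10, min_reads = 10) {
  out <- list()
  for (key in unique(paste(reads$contig, reads$strand))) {
    sub <- reads[paste(reads$contig, reads$strand) == key, , drop = FALSE]
    sub <- sub[order(sub$start, sub$end), , drop = FALSE]
    cur_end <- -Inf; cur_rows <- integer(0)
    flush <- function(rows) {
      if (length(rows) >= min_reads) {
        blk <- sub[rows, , drop = FALSE]
        out[[length(out) + 1L]] <<- list(
          contig = blk$contig[1], start = min(blk$start),
          end = max(blk$end), strand = blk$strand[1],
          n_reads = nrow(blk), reads = blk)
      }
    }
    for (i in seq_len(nrow(sub))) {
      if (sub$start[i] > cur_end + max_gap) {
        flush(cur_rows)
        cur_rows <- i
        cur_end <- sub$end[i]
      } else {
        cur_rows <- c(cur_rows, i)
        cur_end <- max(cur_end, sub$end[i])
      }
    }
    flush(cur_rows)
  }
  out
}

#' Find the highest local read stack of a locus
#'
#' A stack is the set of reads sharing a 5' start position (the Drosha /
#' Dicer anchor; on the minus strand the 5' end is the interval's right
#' coordinate). Scanning 5' to 3' from the first stack, the pointer jumps
#' to any strictly higher stack whose anchor lies within `window` bases
#' downstream of the current anchor, iterating until no higher stack is
#' in the window, which identifies the highest local stack.
#'
#' @param locus a locus from [cluster_loci()].
#' @param window downstream search window in bases.
#' @return list(stack_start, stack_end, height): the selected stack's
#'   read-interval envelope and read count.
#' @export
find_peak_stack <- function(locus, window = 20) {
  r <- locus$reads
  if (nrow(r) == 0) stop("empty locus")
  minus <- locus$strand == "-"
  anchor <- if (minus) -r$end else r$start  # 5' anchor in scan orientation
  stacks <- sort(unique(anchor))
  height <- vapply(stacks, function(a) sum(anchor == a), integer(1))
  cur <- 1L
  repeat {
    inwin <- which(stacks > stacks[cur] & stacks <= stacks[cur] + window &
                     height > height[cur])
    if (length(inwin) == 0) break
    cur <- inwin[which.max(height[inwin])]
  }
  sel <- anchor == stacks[cur]
  list(stack_start = min(r$start[sel]), stack_end = max(r$end[sel]),
       height = sum(sel))
}

#' Excise the two flanked precursor candidates around a read stack
#'
#' The stack interval is excised twice with strand-aware flanks: once
#' with 50 bases upstream and 10 downstream, once with 10 upstream and 50
#' downstream (upstream meaning the 5' side on the read strand), modeling
#' the 5p and 3p placements of the mature sequence within the hairpin.
#' Coordinates are clipped at contig edges and the clip is recorded;
#' minus-strand sequences are reverse-complemented.
#'
#' @param contig contig name.
#' @param stack_start,stack_end stack interval (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param genome a [Biostrings::DNAStringSet].
#' @return list of two candidates (flank_mode `"up50_down10"` and
#'   `"up10_down50"`), each list(contig, start, end, strand, flank_mode,
#'   sequence, clipped).
#' @export
excise_precursors <- function(contig, stack_start, stack_end, strand,
                              genome) {
  if (!contig %in% names(genome))
    stop("contig ", contig, " absent from the genome")
  clen <- Biostrings::width(genome[contig])
  cut <- function(up, down, mode) {
    if (strand == "+") {
      s <- stack_start - up; e <- stack_end + down
    } else {
      s <- stack_start - down; e <- stack_end + up
    }
    cs <- max(0L, s); ce <- min(clen, e)
    seq <- Biostrings::subseq(genome[[contig]], cs + 1L, ce)
    if (strand == "-") seq <- Biostrings::reverseComplement(seq)
    list(contig = contig, start = cs, end = ce, strand = strand,
         flank_mode = mode, sequence = as.character(seq),
         clipped = (cs != s) || (ce != e))
  }
  list(cut(50L, 10L, "up50_down10"), cut(10L, 50L, "up10_down50"))
}

# maximum single-hairpin (non-branching nested) base pairing by dynamic
# programming; Watson-Crick + G.U wobble, minimum loop 3
.pair_ok <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Screen a candidate precursor for a miRNA-like hairpin
#'
#' Built-in structure screen: a dynamic program over the sequence finds
#' the maximum number of base pairs in a single-hairpin (nested,
#' non-branching) structure with Watson--Crick and G-U pairs and a
#' minimum loop of 3 nt. The candidate passes when the stem has at least
#' `min_stem` paired positions and the loop at most `max_loop` bases.
#' This is a base-pair-count screen, not a thermodynamic model; an
#' external folding engine can replace the verdict via `folder`, a
#' function taking the sequence and returning a dot-bracket structure
#' string.
#'
#' @param sequence nucleotide string over A/C/G/U (T accepted), length >=
#'   40.
#' @param min_stem minimum number of paired positions.
#' @param max_loop maximum loop length in bases.
#' @param folder optional external folding function (plug-in point for
#'   RNAfold-compatible tools).
#' @return list(pass, stem_len, loop_len).
#' @export
hairpin_screen <- function(sequence, min_stem = 16, max_loop = 20,
                           folder = NULL) {
  s <- chartr("t", "u", chartr("T", "U", sequence))
  ch <- strsplit(toupper(s), "")[[1]]
  if (!all(ch %in% c("A", "C", "G", "U")))
    stop("sequence contains non-nucleotide characters")
  n <- length(ch)
  if (n < 40) stop("sequence shorter than 40 nt")

  if (!is.null(folder)) {
    db <- strsplit(folder(sequence), "")[[1]]
    stem <- sum(db == "(")
    op <- which(db == "("); clp <- which(db == ")")
    loop <- if (stem > 0) min(clp) - max(op) - 1L else n
    return(list(pass = stem >= min_stem && loop <= max_loop,
                stem_len = stem, loop_len = loop))
  }

  minloop <- 3L
  H <- matrix(0L, n, n)   # H[i,j]: max pairs in i..j, non-branching
  for (len in (minloop + 2L):n) {
    for (i in seq_len(n - len + 1L)) {
      j <- i + len - 1L
      best <- max(H[i + 1L, j], H[i, j - 1L])
      if (.pair_ok(ch[i], ch[j]))
        best <- max(best, H[i + 1L, j - 1L] + 1L)
      H[i, j] <- best
    }
  }
  stem <- H[1L, n]
  if (stem == 0L)
    return(list(pass = FALSE, stem_len = 0L, loop_len = n))
  # traceback to the innermost pair for the loop length
  i <- 1L; j <- n; loop <- n
  while (j - i > minloop) {
    if (.pair_ok(ch[i], ch[j]) && H[i, j] == H[i + 1L, j - 1L] + 1L) {
      loop <- j - i - 1L
      i <- i + 1L; j <- j - 1L
    } else if (H[i, j] == H[i + 1L, j]) {
      i <- i + 1L
    } else {
      j <- j - 1L
    }
  }
  list(pass = stem >= min_stem && loop <= max_loop,
       stem_len = as.integer(stem), loop_len = as.integer(loop))
}

#' Classify a candidate as a mitomiR
#'
#' TRUE when every alignment of the locus's reads lies on the
#' mitochondrial contig.
#'
#' @param locus a locus from [cluster_loci()].
#' @param alignments data.frame (name, contig) listing every alignment of
#'   every read.
#' @param mito_contig mitochondrial contig id, or `NA`.
#' @return logical flag.
#' @export
classify_mitomir <- function(locus, alignments, mito_contig = "chrMT") {
  if (is.na(mito_contig) || !nzchar(mito_contig)) {
    warning("no mitochondrial contig declared; classifying as FALSE")
    return(FALSE)
  }
  al <- alignments[alignments$name %in% locus$reads$name, , drop = FALSE]
  nrow(al) > 0 && all(al$contig == mito_contig)
}

#' Predict putative miRNA precursors from mapped reads
#'
#' End-to-end discovery: filter reads, cluster them into loci, locate
#' each locus's highest local read stack, excise both flanked precursor
#' candidates and screen each for a hairpin. MitomiR loci are reported
#' regardless of the hairpin verdict (the verdict is attached).
#'
#' @param reads,genome,alignments see [preprocess_reads()],
#'   [excise_precursors()], [classify_mitomir()].
#' @param ncrna_mask optional known-ncRNA intervals.
#' @param min_reads,max_gap clustering parameters.
#' @param mito_contig mitochondrial contig id or `NA`.
#' @return data.frame with one row per (locus, flank_mode): contig,
#'   locus_start, locus_end, strand, n_reads, stack_start, stack_end,
#'   stack_height, cand_start, cand_end, flank_mode, hairpin_pass,
#'   stem_len, loop_len, is_mitomir, sequence.
#' @export
discover_mirnas <- function(reads, genome, alignments = NULL,
                            ncrna_mask = NULL, min_reads = 10,
                            max_gap = 10, mito_contig = NA) {
  reads <- preprocess_reads(reads, ncrna_mask = ncrna_mask)
  loci <- cluster_loci(reads, max_gap = max_gap, min_reads = min_reads)
  rows <- list()
  for (lc in loci) {
    pk <- find_peak_stack(lc)
    cands <- excise_precursors(lc$contig, pk$stack_start, pk$stack_end,
                               lc$strand, genome)
    mito <- if (!is.null(alignments) && !is.na(mito_contig))
      classify_mitomir(lc, alignments, mito_contig) else FALSE
    for (cd in cands) {
      hp <- hairpin_screen(cd$sequence)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = lc$contig, locus_start = lc$start, locus_end = lc$end,
        strand = lc$strand, n_reads = lc$n_reads,
        stack_start = pk$stack_start, stack_end = pk$stack_end,
        stack_height = pk$height, cand_start = cd$start,
        cand_end = cd$end, flank_mode = cd$flank_mode,
        hairpin_pass = hp$pass, stem_len = hp$stem_len,
        loop_len = hp$loop_len, is_mitomir = mito,
        sequence = cd$sequence, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}
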