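#' Read assembled reads into a population
#'
#' Reads a FASTA or FASTQ file of assembled amplicons; identical sequences
#' are aggregated into counts. An empty file yields an empty population with
#' a warning.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return a `population` (data.table with `id`, `dna`, `count`).
#' @export
read_population <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e)
      stop("malformed ", format, " record in ", path, ": ",
           conditionMessage(e), call. = FALSE))
  if (!length(x)) {
    warning("no reads in ", path)
    return(.population(data.table(id = character(0), dna = character(0),
                                  count = integer(0)), "observed"))
  }
  dt <- data.table(dna = as.character(x))
  dt <- dt[, .(count = .N), by = dna]
  setorder(dt, -count, dna)
  dt[, id := sprintf("clone%07d", .I)]
  .population(dt[, .(id, dna, count)], "observed")
}

# anchor/segment geometry of a design's framework: 12-nt flanks around each
# diversified region plus the expected conserved inter-anchor spacings
.anchor_set <- function(design, anchor_nt = 12L) {
  fw <- .framework_segments(design$framework)
  last_n <- function(x, n) substr(x, nchar(x) - n + 1, nchar(x))
  list(
    up = list(BC = last_n(fw$fw1, anchor_nt), DE = last_n(fw$fw2, anchor_nt),
              FG = last_n(fw$fw3, anchor_nt)),
    down = list(BC = substr(fw$fw2, 1, anchor_nt),
                DE = substr(fw$fw3, 1, anchor_nt),
                FG = substr(fw$fw4, 1, anchor_nt)),
    # fixed distances between a loop's downstream anchor start and the next
    # loop's upstream anchor end, implied by the conserved framework
    gap2 = nchar(fw$fw2) - anchor_nt,  # BC.down start -> DE.up start
    gap3 = nchar(fw$fw3) - anchor_nt,
    fw = fw, anchor_nt = anchor_nt)
}

#' Classify clones against a design framework
#'
#' A read is `full_length` when all six 12-nt framework anchors flanking the
#' BC, DE and FG regions are found in order, the conserved inter-anchor
#' framework spacings match the reference (so framework indels are caught),
#' every loop segment length is a multiple of three, and the translated
#' coding region contains no stop. Loop indels give `frameshift`, in-frame
#' stops give `stop_codon`, missing or disordered anchors give
#' `unidentified`.
#'
#' @param dna character vector of read sequences.
#' @param design a [library_design()].
#' @return character vector of classifications.
#' @export
classify_clone <- function(dna, design) {
  .process_reads(dna, design)$classification
}

# exhaustive anchor resolution for one read: pick occurrence combinations
# consistent with the conserved framework spacings, preferring in-frame
# loop segments. Returns c(u1, d1, u2, d2, u3, d3) or NULL.
.resolve_anchors <- function(read, an) {
  occ <- function(pat) {
    p <- gregexpr(pat, read, fixed = TRUE)[[1]]
    if (p[1] < 0) integer(0) else as.integer(p)
  }
  k <- an$anchor_nt
  U1 <- occ(an$up$BC); D1 <- occ(an$down$BC)
  D2 <- occ(an$down$DE); D3 <- occ(an$down$FG)
  U2 <- occ(an$up$DE); U3 <- occ(an$up$FG)
  best <- NULL
  for (a in U1) for (b in D1[D1 >= a + k]) {
    u2 <- b + an$gap2
    if (!u2 %in% U2) next
    for (cc in D2[D2 >= u2 + k]) {
      u3 <- cc + an$gap3
      if (!u3 %in% U3) next
      for (dd in D3[D3 >= u3 + k]) {
        cand <- c(a, b, u2, cc, u3, dd)
        inframe <- (b - a - k) %% 3 == 0 && (cc - u2 - k) %% 3 == 0 &&
          (dd - u3 - k) %% 3 == 0
        if (inframe) return(cand)
        if (is.null(best)) best <- cand
      }
    }
  }
  best
}

# vectorised workhorse: classification + loop extraction
.process_reads <- function(dna, design) {
  an <- .anchor_set(design)
  k <- an$anchor_nt
  pos <- function(pat) {
    p <- regexpr(pat, dna, fixed = TRUE)
    ifelse(p > 0, as.integer(p), NA_integer_)
  }
  u1 <- pos(an$up$BC);  d1 <- pos(an$down$BC)
  u2 <- pos(an$up$DE);  d2 <- pos(an$down$DE)
  u3 <- pos(an$up$FG);  d3 <- pos(an$down$FG)
  n <- length(dna)
  # fast path takes the first occurrence of each anchor; when that violates
  # the rigid framework spacing (an anchor-like 12-mer can arise by chance
  # inside a loop), re-resolve from all occurrences jointly
  susp <- which(!(!is.na(u1) & !is.na(d1) & !is.na(u2) & !is.na(d2) &
                    !is.na(u3) & !is.na(d3) &
                    u1 < d1 & d1 <= u2 & u2 < d2 & d2 <= u3 & u3 < d3 &
                    (u2 - d1) == an$gap2 & (u3 - d2) == an$gap3 &
                    (d1 - u1 - k) %% 3 == 0 & (d2 - u2 - k) %% 3 == 0 &
                    (d3 - u3 - k) %% 3 == 0))
  for (i in susp) {
    fix <- .resolve_anchors(dna[i], an)
    if (!is.null(fix)) {
      u1[i] <- fix[1]; d1[i] <- fix[2]; u2[i] <- fix[3]
      d2[i] <- fix[4]; u3[i] <- fix[5]; d3[i] <- fix[6]
    }
  }
  cls <- rep("unidentified", n)
  ok <- !is.na(u1) & !is.na(d1) & !is.na(u2) & !is.na(d2) &
        !is.na(u3) & !is.na(d3) &
        u1 < d1 & d1 <= u2 & u2 < d2 & d2 <= u3 & u3 < d3
  lbc <- d1 - (u1 + k)
  lde <- d2 - (u2 + k)
  lfg <- d3 - (u3 + k)
  frame_ok <- ok & (u2 - d1) == an$gap2 & (u3 - d2) == an$gap3 &
    lbc >= 0 & lde >= 0 & lfg >= 0 &
    lbc %% 3 == 0 & lde %% 3 == 0 & lfg %% 3 == 0
  cls[ok & !frame_ok] <- "frameshift"
  BC <- DE <- FG <- rep(NA_character_, n)
  prot_fw <- rep(NA_character_, n)
  idx <- which(frame_ok)
  if (length(idx)) {
    bc <- substr(dna[idx], u1[idx] + k, d1[idx] - 1)
    de <- substr(dna[idx], u2[idx] + k, d2[idx] - 1)
    fg <- substr(dna[idx], u3[idx] + k, d3[idx] - 1)
    tr_var <- function(x) {  # translate variable-length segments by group
      out <- character(length(x))
      for (L in unique(nchar(x))) {
        sel <- nchar(x) == L
        out[sel] <- if (L == 0) "" else translate_dna(x[sel])
      }
      out
    }
    BC[idx] <- tr_var(bc)
    DE[idx] <- tr_var(de)
    FG[idx] <- tr_var(fg)
    # conserved framework portions of the read, translated in the anchor
    # frame: between-loop segments plus whatever prefix/suffix is in frame
    fw2 <- substr(dna[idx], d1[idx], u2[idx] + k - 1)
    fw3 <- substr(dna[idx], d2[idx], u3[idx] + k - 1)
    pre_len <- ((u1[idx] - 1) %/% 3) * 3
    fw1 <- substr(dna[idx], u1[idx] + k - 1 - (pre_len + k) + 1,
                  u1[idx] + k - 1)
    post_av <- nchar(dna[idx]) - d3[idx] + 1
    post_len <- (post_av %/% 3) * 3
    fw4 <- substr(dna[idx], d3[idx], d3[idx] + post_len - 1)
    prot_fw[idx] <- paste0(tr_var(fw1), tr_var(fw2), tr_var(fw3),
                           tr_var(fw4))
    stop_hit <- grepl("*", BC[idx], fixed = TRUE) |
      grepl("*", DE[idx], fixed = TRUE) |
      grepl("*", FG[idx], fixed = TRUE) |
      grepl("*", prot_fw[idx], fixed = TRUE)
    cls[idx] <- ifelse(stop_hit, "stop_codon", "full_length")
  }
  list(classification = cls, BC = BC, DE = DE, FG = FG,
       framework = prot_fw,
       len_BC = ifelse(is.na(BC), NA_integer_, nchar(BC)),
       len_DE = ifelse(is.na(DE), NA_integer_, nchar(DE)),
       len_FG = ifelse(is.na(FG), NA_integer_, nchar(FG)))
}

#' Extract diversified loops from a read
#'
#' @param dna character vector of reads.
#' @param design a [library_design()].
#' @return data.table with `classification` and, for full-length reads, the
#'   translated `BC`, `DE`, `FG` loop sequences.
#' @export
extract_loops <- function(dna, design) {
  as.data.table(.process_reads(dna, design)[
    c("classification", "BC", "DE", "FG")])
}

#' Align a loop sequence to reference site labels
#'
#' Maps the residues of a loop to the design's site labels for the matching
#' length variant: fixed flank residues keep their reference labels,
#' inserted mid-loop positions get insertion-coded labels (e.g. `"28a"`),
#' and deleted positions are simply absent. A length matching no variant
#' returns `NULL` (the clone is reported unaligned and excluded from
#' sitewise counts).
#'
#' @param loop_seq loop amino-acid string.
#' @param loop_id `"BC"`, `"DE"` or `"FG"`.
#' @param design a [library_design()].
#' @return named character vector (site label -> residue), or `NULL`.
#' @export
align_loop <- function(loop_seq, loop_id, design) {
  labs <- loop_site_labels(design, loop_id, nchar(loop_seq))
  if (is.null(labs)) return(NULL)
  setNames(strsplit(loop_seq, "", fixed = TRUE)[[1]], labs)
}

#' Process a population into a clone table
#'
#' Runs classification and loop extraction over a whole population and
#' attaches alignment status (whether each loop length matches a design
#' length variant).
#'
#' @param pop a `population` (simulated or read from file).
#' @param design a [library_design()].
#' @return a `clone_table`: data.table with id, count, classification, loop
#'   sequences and lengths, framework translation and an `aligned` flag.
#' @export
process_population <- function(pop, design) {
  res <- .process_reads(pop$dna, design)
  dt <- data.table(id = pop$id, count = pop$count,
                   classification = res$classification,
                   BC = res$BC, DE = res$DE, FG = res$FG,
                   len_BC = res$len_BC, len_DE = res$len_DE,
                   len_FG = res$len_FG, framework = res$framework)
  known <- function(loop, lens) {
    lens %in% vapply(unique(lens[!is.na(lens)]), function(L)
      if (is.null(loop_site_labels(design, loop, L))) NA_integer_ else L,
      integer(1))
  }
  dt[, aligned := classification == "full_length" &
       known("BC", len_BC) & known("DE", len_DE) & known("FG", len_FG)]
  n_un <- sum(dt$classification == "full_length" & !dt$aligned)
  if (n_un)
    message(n_un, " full-length clone(s) have loop lengths matching no ",
            "design variant; excluded from sitewise counts")
  structure(dt, class = c("clone_table", class(dt)), design = design,
            label = attr(pop, "label"))
}
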