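# run expr under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.population <- function(dt, label, design = NULL) {
  setDT(dt)
  structure(dt, class = c("population", class(dt)),
            label = label, design = design)
}

#' @export
print.population <- function(x, ...) {
  cat("<population>", attr(x, "label"), "-", nrow(x), "clones,",
      sum(x$count), "reads\n")
  invisible(x)
}

# framework DNA cut into the four conserved segments around the loops
.framework_segments <- function(framework) {
  rg <- framework$loops
  cut_nt <- function(first_res, last_res)
    substr(framework$dna, (first_res - 1) * 3 + 1, last_res * 3)
  n <- nchar(framework$protein)
  list(fw1 = cut_nt(1, rg$BC[1] - 1),
       fw2 = cut_nt(rg$BC[2] + 1, rg$DE[1] - 1),
       fw3 = cut_nt(rg$DE[2] + 1, rg$FG[1] - 1),
       fw4 = cut_nt(rg$FG[2] + 1, n))
}

#' Site labels of a loop length class
#'
#' @param design a [library_design()].
#' @param loop_id `"BC"`, `"DE"` or `"FG"`.
#' @param len loop length (residues).
#' @return character vector of site labels, or `NULL` if no length variant
#'   of the design matches `len`.
#' @export
loop_site_labels <- function(design, loop_id, len) {
  for (s in design$sublibraries) {
    for (v in s$loops[[loop_id]]$variants) {
      if (length(v$sites) == len) return(variant_labels(v))
    }
  }
  NULL
}

# sample m loop sequences from one variant; returns list(aa=, dna=)
.sample_variant <- function(variant, m) {
  gc <- .genetic_code()
  nt <- c("A", "C", "G", "T")
  aa_cols <- vector("list", length(variant$sites))
  dna_cols <- vector("list", length(variant$sites))
  for (j in seq_along(variant$sites)) {
    sp <- variant$sites[[j]]
    if (sp$kind == "degenerate_codon") {
      cod <- paste0(sample(nt, m, TRUE, sp$mix[1, ]),
                    sample(nt, m, TRUE, sp$mix[2, ]),
                    sample(nt, m, TRUE, sp$mix[3, ]))
      aa_cols[[j]] <- unname(gc[cod])
      dna_cols[[j]] <- cod
    } else {
      aas <- names(sp$probs)
      aa <- if (length(aas) == 1) rep(aas, m)
            else sample(aas, m, TRUE, sp$probs)
      aa_cols[[j]] <- aa
      dna_cols[[j]] <- unname(.CODON_OF[aa])
    }
  }
  list(aa = do.call(paste0, aa_cols), dna = do.call(paste0, dna_cols))
}

#' Sample a naive population from a library design
#'
#' Draws `n` independent clones: a sublibrary by pool weight, a length
#' variant per loop by prior weight, then residues site by site. Degenerate
#' codons are sampled at the nucleotide level, so stop codons arise
#' naturally at their designed rate. The returned table carries the full
#' clone DNA plus ground-truth columns (sublibrary, per-loop amino-acid
#' strings with `"*"` for sampled stops, loop lengths).
#'
#' @param design a [library_design()].
#' @param n number of clones (>= 1).
#' @param seed RNG seed; identical seed and inputs give identical output.
#' @param label population label.
#' @return a `population` (a data.table with one row per clone, `count = 1`).
#' @export
sample_population <- function(design, n, seed, label = "naive") {
  stopifnot(n >= 1)
  .with_seed(seed, {
    K <- length(design$sublibraries)
    pw <- vapply(design$sublibraries, function(s) s$weight, numeric(1))
    sub <- sample.int(K, n, replace = TRUE, prob = pw)
    loops <- c("BC", "DE", "FG")
    aa <- lapply(setNames(nm = loops), function(l) character(n))
    dna <- lapply(setNames(nm = loops), function(l) character(n))
    for (k in seq_len(K)) {
      idx <- which(sub == k)
      if (!length(idx)) next
      for (loop in loops) {
        ld <- design$sublibraries[[k]]$loops[[loop]]
        vw <- vapply(ld$variants, function(v) v$weight, numeric(1))
        vi <- sample.int(length(vw), length(idx), TRUE, prob = vw)
        for (v in seq_along(ld$variants)) {
          take <- idx[vi == v]
          if (!length(take)) next
          smp <- .sample_variant(ld$variants[[v]], length(take))
          aa[[loop]][take] <- smp$aa
          dna[[loop]][take] <- smp$dna
        }
      }
    }
    fw <- .framework_segments(design$framework)
    full <- paste0(fw$fw1, dna$BC, fw$fw2, dna$DE, fw$fw3, dna$FG, fw$fw4)
    dt <- data.table(
      id = sprintf("clone%07d", seq_len(n)), dna = full, count = 1L,
      sublib = sub, BC = aa$BC, DE = aa$DE, FG = aa$FG,
      len_BC = nchar(aa$BC), len_DE = nchar(aa$DE), len_FG = nchar(aa$FG),
      n_sub = 0L, n_ins = 0L, n_del = 0L)
    .population(dt, label, design)
  })
}

#' Inject sequencing/synthesis errors
#'
#' Applies per-base substitutions and single-base insertions/deletions to
#' each clone record independently; truth columns `n_sub`, `n_ins`, `n_del`
#' record the injected events. An indel makes the clone a frameshift for
#' downstream classification and disqualifies it from selection.
#'
#' @param pop a `population`.
#' @param sub_rate,indel_rate per-base rates, both in `[0, 0.2]`.
#' @param seed RNG seed.
#' @return a new `population`.
#' @export
inject_errors <- function(pop, sub_rate, indel_rate, seed) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.2,
            indel_rate >= 0, indel_rate <= 0.2)
  nt <- c("A", "C", "G", "T")
  .with_seed(seed, {
    dt <- data.table::copy(pop)
    lens <- nchar(dt$dna)
    nsub <- rbinom(nrow(dt), lens, sub_rate)
    nind <- rbinom(nrow(dt), lens, indel_rate)
    touch <- which(nsub + nind > 0)
    for (i in touch) {
      s <- strsplit(dt$dna[i], "", fixed = TRUE)[[1]]
      if (nsub[i] > 0) {
        pos <- sample.int(length(s), nsub[i])
        for (p in pos) s[p] <- sample(setdiff(nt, s[p]), 1)
      }
      ins <- 0L; del <- 0L
      if (nind[i] > 0) {
        for (e in seq_len(nind[i])) {
          p <- sample.int(length(s), 1)
          if (runif(1) < 0.5) {
            s <- append(s, sample(nt, 1), after = p)
            ins <- ins + 1L
          } else {
            s <- s[-p]
            del <- del + 1L
          }
        }
      }
      data.table::set(dt, i, "dna", paste(s, collapse = ""))
      data.table::set(dt, i, "n_ins", dt$n_ins[i] + ins)
      data.table::set(dt, i, "n_del", dt$n_del[i] + del)
    }
    dt[, n_sub := n_sub + nsub]
    .population(dt, attr(pop, "label"), attr(pop, "design"))
  })
}

#' Planted sitewise selection models
#'
#' Selection acts multiplicatively on a clone's summed log-fitness: per-site
#' amino-acid contributions plus optional per-loop length contributions,
#' scaled by `stringency`. Clones containing a sampled stop or an injected
#' indel are never selected (log-fitness `-Inf`).
#'
#' @param site_scores named list: site label -> named numeric
#'   (amino acid -> log-fitness contribution). Unlisted residues score 0.
#' @param length_scores optional named list: loop id -> named numeric
#'   (loop length as character -> log-fitness).
#' @param rounds number of selection rounds (>= 0).
#' @param stringency scale factor applied to the summed log-fitness.
#' @return an object of class `selection_model`.
#' @export
selection_model <- function(site_scores = list(), length_scores = NULL,
                            rounds = 1, stringency = 1) {
  stopifnot(rounds >= 0, is.finite(stringency))
  for (v in site_scores) stopifnot(all(is.finite(v)))
  if (!is.null(length_scores))
    for (v in length_scores) stopifnot(all(is.finite(v)))
  structure(list(site_scores = site_scores, length_scores = length_scores,
                 rounds = rounds, stringency = stringency),
            class = "selection_model")
}

# per-clone log fitness under a model (uses truth columns + design labels)
.log_fitness <- function(pop, model) {
  design <- attr(pop, "design")
  if (is.null(design))
    stop("population carries no design; selection needs truth labels",
         call. = FALSE)
  s <- numeric(nrow(pop))
  for (loop in c("BC", "DE", "FG")) {
    lens <- pop[[paste0("len_", loop)]]
    for (len in unique(lens)) {
      idx <- which(lens == len)
      labs <- loop_site_labels(design, loop, len)
      mat <- .char_matrix(pop[[loop]][idx])
      for (j in seq_along(labs)) {
        sc <- model$site_scores[[labs[j]]]
        if (is.null(sc)) next
        add <- sc[mat[, j]]
        add[is.na(add)] <- 0
        s[idx] <- s[idx] + add
      }
      ls <- model$length_scores[[loop]]
      if (!is.null(ls) && !is.na(ls[as.character(len)]))
        s[idx] <- s[idx] + ls[[as.character(len)]]
    }
  }
  has_stop <- grepl("*", pop$BC, fixed = TRUE) |
    grepl("*", pop$DE, fixed = TRUE) | grepl("*", pop$FG, fixed = TRUE)
  s[has_stop] <- -Inf
  s[(pop$n_ins + pop$n_del) > 0] <- -Inf
  s
}

#' Apply planted selection to a population
#'
#' Per round, clone counts are resampled from a multinomial with
#' probabilities proportional to `count * exp(stringency * log-fitness)`;
#' the total read count is preserved exactly.
#'
#' @param pop a `population` produced by [sample_population()] (optionally
#'   after [inject_errors()]).
#' @param model a [selection_model()].
#' @param seed RNG seed.
#' @param label label of the output population.
#' @return a `population` with updated counts (zero-count clones dropped).
#' @export
simulate_selection <- function(pop, model, seed, label = "binder") {
  stopifnot(inherits(model, "selection_model"), nrow(pop) >= 1)
  .with_seed(seed, {
    s <- .log_fitness(pop, model)
    total <- sum(pop$count)
    counts <- as.numeric(pop$count)
    fit <- exp(model$stringency * s)
    for (r in seq_len(model$rounds)) {
      w <- counts * fit
      if (!any(w > 0)) stop("no selectable clones", call. = FALSE)
      counts <- as.numeric(rmultinom(1, total, w))
    }
    dt <- data.table::copy(pop)
    dt[, count := as.integer(counts)]
    dt <- dt[count > 0]
    .population(dt, label, attr(pop, "design"))
  })
}

#' Write a population to FASTA/FASTQ
#'
#' FASTA writes one record per clone with the read count and truth labels
#' encoded in the header (`id|count=..|sublib=..|len=..`); FASTQ writes
#' `count` identical records per clone with uniform quality `"I"`, so that
#' reading the file back recovers counts exactly.
#'
#' @param pop a `population`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  hdr <- sprintf("%s|count=%d", pop$id, pop$count)
  if (!is.null(pop$sublib))
    hdr <- sprintf("%s|sublib=%d|len=%d,%d,%d", hdr, pop$sublib,
                   pop$len_BC, pop$len_DE, pop$len_FG)
  if (format == "fasta") {
    x <- Biostrings::DNAStringSet(pop$dna)
    names(x) <- hdr
    Biostrings::writeXStringSet(x, path)
  } else {
    idx <- rep(seq_len(nrow(pop)), pop$count)
    x <- Biostrings::DNAStringSet(pop$dna[idx])
    names(x) <- sprintf("%s|read%d", hdr[idx], sequence(pop$count))
    qual <- Biostrings::BStringSet(strrep("I", nchar(pop$dna[idx])))
    Biostrings::writeQualityScaledXStringSet(
      Biostrings::QualityScaledDNAStringSet(
        x, Biostrings::PhredQuality(qual)), path)
  }
  invisible(path)
}
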