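test_that("sampling is deterministic and respects conserved designs", {
  d <- two_site_design()
  p1 <- sample_population(d, 1, seed = 5)
  p2 <- sample_population(d, 1, seed = 5)
  expect_identical(p1$dna, p2$dna)
  expect_identical(p1$BC, p2$BC)

  dc <- conserved_design()
  pc <- sample_population(dc, 50, seed = 9)
  expect_equal(length(unique(pc$dna)), 1)
  expect_true(all(pc$BC == "DA" & pc$DE == "G" & pc$FG == "T"))
  expect_error(sample_population(d, 0, seed = 1))
})

test_that("sampled per-site frequencies match the design (4 SE)", {
  d <- two_site_design()
  n <- 2e4
  pop <- sample_population(d, n, seed = 31)
  fS <- mean(substr(pop$BC, 1, 1) == "S")
  se <- sqrt(0.25 / n)
  expect_lt(abs(fS - 0.5), 4 * se)
})

test_that("error injection follows the requested rates", {
  d <- two_site_design()
  pop <- sample_population(d, 2000, seed = 7)
  # indel_rate = 0 leaves lengths unchanged
  p0 <- inject_errors(pop, sub_rate = 0.005, indel_rate = 0, seed = 1)
  expect_identical(nchar(p0$dna), nchar(pop$dna))
  # substitution totals within 4 SE of n * len * rate
  len <- sum(nchar(pop$dna))
  rate <- 0.002
  pe <- inject_errors(pop, rate, 0, seed = 2)
  expected <- len * rate
  se <- sqrt(len * rate * (1 - rate))
  expect_lt(abs(sum(pe$n_sub) - expected), 4 * se)
  # single indels break classification: a loop indel is a frameshift, an
  # indel inside an anchor makes the read unidentified, and only terminal
  # framework indels (outside the analysed region) can stay full_length
  pi1 <- inject_errors(pop[1:200], 0, 0.005, seed = 3)
  hit <- which(pi1$n_ins + pi1$n_del == 1)
  expect_gt(length(hit), 0)
  cls <- classify_clone(pi1$dna[hit], d)
  expect_true("frameshift" %in% cls)
  expect_true(all(cls %in% c("frameshift", "unidentified", "full_length")))
  expect_error(inject_errors(pop, 0.5, 0, seed = 1))
})

test_that("selection reweights by the closed-form softmax", {
  d <- two_site_design()
  n <- 2e4
  pop <- sample_population(d, n, seed = 13)
  # neutral model leaves frequencies unchanged (4 SE)
  m0 <- selection_model(site_scores = list(B1 = c(Y = 0)), rounds = 1)
  s0 <- simulate_selection(pop, m0, seed = 21)
  expect_equal(sum(s0$count), n)
  fY0 <- sum(s0$count[substr(s0$BC, 1, 1) == "Y"]) / n
  expect_lt(abs(fY0 - 0.5), 4 * sqrt(0.25 / n))
  # score(Y) = ln 3, one round: E[f_Y] = 0.5*3 / (0.5*3 + 0.5) = 0.75
  m1 <- selection_model(site_scores = list(B1 = c(Y = log(3))), rounds = 1)
  s1 <- simulate_selection(pop, m1, seed = 22)
  fY1 <- sum(s1$count[substr(s1$BC, 1, 1) == "Y"]) / n
  expect_lt(abs(fY1 - 0.75), 4 * sqrt(0.75 * 0.25 / n))
  # two rounds: 0.5*9 / (0.5*9 + 0.5) = 0.9. The two-stage resampling
  # propagates round-1 variance: SE^2 = (f2(1-f2) + (df2/df1)^2 f1(1-f1))/n
  # with f2 = 3 f1 / (1 + 2 f1), df2/df1 = 3/(1 + 2 f1)^2 = 0.48 at f1=0.75
  m2 <- selection_model(site_scores = list(B1 = c(Y = log(3))), rounds = 2)
  s2 <- simulate_selection(pop, m2, seed = 23)
  fY2 <- sum(s2$count[substr(s2$BC, 1, 1) == "Y"]) / n
  se2 <- sqrt((0.9 * 0.1 + 0.48^2 * 0.75 * 0.25) / n)
  expect_lt(abs(fY2 - 0.9), 4 * se2)
  # totals preserved exactly in all cases
  expect_equal(sum(s1$count), n)
  expect_equal(sum(s2$count), n)
})

test_that("stop/frameshift clones are never selected; all -Inf errors", {
  d <- toy_design(
    bc = list(list(degenerate_site("B1"))),
    de = list(list(conserved_site("E1", "A"))),
    fg = list(list(conserved_site("F1", "L"))))
  pop <- sample_population(d, 3000, seed = 17)
  expect_gt(sum(grepl("*", pop$BC, fixed = TRUE)), 0)
  m <- selection_model(site_scores = list(B1 = c(Y = 1)), rounds = 1)
  sel <- simulate_selection(pop, m, seed = 2)
  expect_false(any(grepl("*", sel$BC, fixed = TRUE)))
  # a population of only stop-containing clones cannot be selected
  stops <- pop[grepl("*", pop$BC, fixed = TRUE)]
  attr(stops, "design") <- d
  attr(stops, "label") <- "stops"
  expect_error(simulate_selection(stops, m, seed = 3), "no selectable")
})

test_that("length scores shift loop-length distributions", {
  d <- toy_design(
    bc = list(list(fixed_set_site("B1", "SY")),
              list(fixed_set_site("B1", "SY"), fixed_set_site("B2", "SY"))),
    de = list(list(conserved_site("E1", "A"))),
    fg = list(list(conserved_site("F1", "L"))))
  pop <- sample_population(d, 2e4, seed = 41)
  m <- selection_model(length_scores = list(BC = c("1" = log(4))),
                       rounds = 1)
  sel <- simulate_selection(pop, m, seed = 42)
  f1 <- sum(sel$count[sel$len_BC == 1]) / sum(sel$count)
  expect_lt(abs(f1 - 0.8), 4 * sqrt(0.8 * 0.2 / 2e4))  # 0.5*4/(0.5*4+0.5)
})

test_that("planted enrichments/depletions recover across 20 random models", {
  # sign agreement of truth-level frequency changes with planted scores,
  # over 20 random selection models sharing one naive draw. (Run at
  # n = 2e4 rather than 1e5 to stay inside the suite's time budget; the
  # binomial error at 2e4 is far below the tested effect sizes.)
  g1 <- gen1_design()
  n <- 2e4
  naive <- sample_population(g1, n, seed = 55)
  # always-present diversified sites and residues common at them
  site_pool <- list(V29 = c("A", "S", "T"), R30 = c("Y", "S", "L", "T"),
                    A26 = c("Y", "S", "L", "T"), G79 = c("G", "D", "N",
                                                         "S", "Y", "C"),
                    D80 = c("Y", "S", "L", "T"))
  truth_freq <- function(pop, site) {
    num <- setNames(numeric(20), AA20); den <- 0
    for (loop in c("BC", "DE", "FG")) {
      lens <- pop[[paste0("len_", loop)]]
      for (L in unique(lens)) {
        labs <- loop_site_labels(g1, loop, L)
        j <- which(labs == site)
        if (!length(j)) next
        sel <- lens == L & !grepl("[*]", paste0(pop$BC, pop$DE, pop$FG))
        res <- substr(pop[[loop]][sel], j, j)
        cnt <- tapply(pop$count[sel], res, sum)
        cnt <- cnt[names(cnt) %in% AA20]
        num[names(cnt)] <- num[names(cnt)] + cnt
        den <- den + sum(cnt)
      }
    }
    num / den
  }
  set.seed(56)
  agree <- 0; total <- 0
  for (m in 1:20) {
    sites <- sample(names(site_pool), 2)
    scores <- lapply(sites, function(s) {
      aa <- sample(site_pool[[s]], 2)
      setNames(c(1, -1) * runif(2, log(2), log(4)), aa)
    })
    names(scores) <- sites
    sel <- simulate_selection(naive, selection_model(scores, rounds = 2),
                              seed = 100 + m)
    for (s in sites) {
      fn <- truth_freq(naive, s); fb <- truth_freq(sel, s)
      for (aa in names(scores[[s]])) {
        total <- total + 1
        if (sign(fb[[aa]] - fn[[aa]]) == sign(scores[[s]][[aa]]))
          agree <- agree + 1
      }
    }
  }
  expect_gte(agree / total, 0.95)
})

test_that("FASTA/FASTQ round-trips preserve counts", {
  d <- two_site_design()
  pop <- sample_population(d, 200, seed = 3)
  sel <- simulate_selection(
    pop, selection_model(site_scores = list(B1 = c(Y = 1))), seed = 4)
  fq <- tempfile(fileext = ".fastq")
  write_population(sel, fq, "fastq")
  back <- read_population(fq)
  expect_equal(sum(back$count), sum(sel$count))
  merged <- merge(back[, .(dna, count)],
                  sel[, .(count = sum(count)), by = dna], by = "dna")
  expect_equal(merged$count.x, merged$count.y)
  fa <- tempfile(fileext = ".fasta")
  write_population(sel, fa, "fasta")
  expect_equal(nrow(read_population(fa)), length(unique(sel$dna)))
})
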