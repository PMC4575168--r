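# shared fixtures: tiny designs, PDB writers, frequency-matrix builders and
# independent oracles. Everything is generated in code; no binary fixtures.

suppressPackageStartupMessages(library(data.table))

# -- tiny library designs -----------------------------------------------------

# a one-sublibrary design over a short synthetic framework. Each loop is a
# list of length variants; a variant is a list of site_spec objects.
toy_design <- function(bc, de, fg, generation = "toy") {
  mk_loop <- function(loop_id, variants) {
    loop_design(loop_id, lapply(variants, function(v)
      list(sites = v, weight = 1)))
  }
  # a diverse framework so the 12-nt anchors are unique in the gene
  prot <- "MKTAYIAKQRDISFVKWHESRNLPEERC"
  codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
             G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTG",
             M = "ATG", N = "AAT", P = "CCG", Q = "CAG", R = "CGT",
             S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  aas <- strsplit(prot, "", fixed = TRUE)[[1]]
  framework <- list(protein = prot,
                    dna = paste(codon[aas], collapse = ""),
                    loops = list(BC = c(5L, 6L), DE = c(12L, 13L),
                                 FG = c(19L, 21L)))
  library_design(generation, list(list(
    loops = list(BC = mk_loop("BC", bc), DE = mk_loop("DE", de),
                 FG = mk_loop("FG", fg)), weight = 1)), framework)
}

# two diversified {S,Y} sites in BC, conserved single-residue DE/FG loops
two_site_design <- function() {
  toy_design(
    bc = list(list(fixed_set_site("B1", "SY"), fixed_set_site("B2", "SY"))),
    de = list(list(conserved_site("E1", "A"))),
    fg = list(list(conserved_site("F1", "L"))))
}

# all-conserved design (every clone identical)
conserved_design <- function() {
  toy_design(
    bc = list(list(conserved_site("B1", "D"), conserved_site("B2", "A"))),
    de = list(list(conserved_site("E1", "G"))),
    fg = list(list(conserved_site("F1", "T"))))
}

# -- frequency matrices -------------------------------------------------------

as_fm <- function(m) {
  structure(m, class = "frequency_matrix",
            effective_weight = setNames(rowSums(m), rownames(m)))
}

random_fm <- function(n_sites, prefix = "s", rng = NULL) {
  m <- matrix(rexp(n_sites * 20), n_sites, 20,
              dimnames = list(paste0(prefix, seq_len(n_sites)), AA20))
  as_fm(m / rowSums(m))
}

point_fm <- function(probs_by_site) {
  m <- matrix(0, length(probs_by_site), 20,
              dimnames = list(names(probs_by_site), AA20))
  for (s in names(probs_by_site)) m[s, names(probs_by_site[[s]])] <-
      probs_by_site[[s]]
  as_fm(m)
}

# -- independent oracles ------------------------------------------------------

# brute-force 64-codon enumeration, independent of codon_aa_distribution
oracle_codon_dist <- function(p1, p2, p3) {
  nt <- c("A", "C", "G", "T")
  names(p1) <- names(p2) <- names(p3) <- nt
  gc <- Biostrings::GENETIC_CODE
  out <- setNames(numeric(21), AA21)
  for (a in nt) for (b in nt) for (d in nt) {
    aa <- gc[[paste0(a, b, d)]]
    out[aa] <- out[aa] + p1[[a]] * p2[[b]] * p3[[d]]
  }
  out
}

# independent global-alignment identity oracle (match 1, mismatch 0, gap 0;
# among equal-score optima prefer the fewest gaps): brute-force R dynamic
# programme over (matches, aligned pairs)
oracle_identity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  if (n + m == 0) return(1)
  M <- matrix(0, n + 1, m + 1)  # matches * 1000 + aligned pairs
  for (i in seq_len(n)) for (j in seq_len(m)) {
    diag_v <- M[i, j] + 1 + if (x[i] == y[j]) 1000 else 0
    M[i + 1, j + 1] <- max(diag_v, M[i, j + 1], M[i + 1, j])
  }
  v <- M[n + 1, m + 1]
  matches <- v %/% 1000
  pairs <- v %% 1000
  matches / (n + m - pairs)
}

# forward-constructed objective with planted weights (echoing the reported
# 62% complementarity / 30% stability / 8% natural-frequency split)
planted_fit_case <- function(seed, noise_sd = 0, n_sites = 25) {
  set.seed(seed)
  inputs <- list(complementarity = random_fm(n_sites),
                 stability = random_fm(n_sites),
                 homolog = random_fm(n_sites))
  eps <- setNames(runif(n_sites), rownames(inputs[[1]]))
  alpha <- c(0.62, 0.30, 0.08)
  beta <- c(0.10, -0.04, -0.06)
  obj <- matrix(0, n_sites, 20, dimnames = dimnames(inputs[[1]]))
  for (k in 1:3)
    obj <- obj + (alpha[k] + beta[k] * eps) * unclass(inputs[[k]])
  if (noise_sd > 0) obj <- obj + matrix(rnorm(n_sites * 20, 0, noise_sd),
                                        n_sites, 20)
  list(objective = as_fm(obj), inputs = inputs, eps = eps,
       alpha = alpha, beta = beta)
}

# -- toy PDB structures -------------------------------------------------------

write_pdb <- function(path, atoms, extra_lines = character(0)) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), atoms$atom, atoms$resname, atoms$chain,
    atoms$resno, atoms$x, atoms$y, atoms$z, atoms$element)
  writeLines(c(lines, extra_lines, "END"), path)
  path
}

pdb_atom <- function(atom, resno, x, y, z, resname = "ALA", chain = "A",
                     element = substr(atom, 1, 1)) {
  data.frame(atom = atom, resname = resname, chain = chain, resno = resno,
             x = x, y = y, z = z, element = element,
             stringsAsFactors = FALSE)
}
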