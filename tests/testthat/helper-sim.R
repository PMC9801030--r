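## Shared fixtures, built in code and cached for the session.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

## small SNP-only parental pair (100 kb)
tiny_parents <- function() fixture("tiny_parents",
  make_parents(length = 1e5L, snp_rate = 1 / 500, seed = 42L))

## parental pair with one of each artifact source (200 kb)
artifact_parents <- function() fixture("artifact_parents",
  make_parents(
    length = 2e5L, snp_rate = 1 / 200, indel_rate = 1 / 10000,
    sv_spec = list(
      list(class = "deletion", pos = 50000, len = 1500, divergence = 4,
           paralog = TRUE),
      list(class = "duplication", pos = 120000, len = 2500,
           divergence = 3, true_snp = TRUE)),
    repeat_spec = list(list(pos = 80000, unit = "AG", copies = 10,
                            alt_copy_delta = -1)),
    seed = 7L))

artifact_sim <- function() fixture("artifact_sim",
  write_alignments(artifact_parents(), depth = 20, seed = 11L))

## random DNA string helper for constructed fixtures
rand_seq <- function(n, seed = 1L) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""))
}

## quick variant-table builder for filter unit tests
vt <- function(pos, ref = "A", alt = "T", class = "SNP", depth = 20L,
               p_supp = 0L, a_supp = depth, genotype = "alt-hom",
               qual = 60, filter = "", chrom = "chr1") {
  n <- length(pos)
  variant_table(rep_len(chrom, n), pos, rep_len(ref, n), rep_len(alt, n),
                rep_len(class, n), rep_len(depth, n), rep_len(p_supp, n),
                rep_len(a_supp, n), rep_len(genotype, n),
                rep_len(qual, n), rep_len(filter, n))
}

## brute-force diallelic genotype posterior (independent oracle):
## plain products over observations, no log-space tricks
oracle_posterior <- function(bases, quals, ref, alt, het_prior = 1e-3) {
  e <- 10^(-quals / 10)
  p_obs <- function(allele) ifelse(bases == allele, 1 - e, e / 3)
  lik <- c(rr = prod(p_obs(ref)),
           ra = prod((p_obs(ref) + p_obs(alt)) / 2),
           aa = prod(p_obs(alt)))
  pri <- c(rr = 1 - 1.5 * het_prior, ra = het_prior, aa = het_prior / 2)
  post <- lik * pri / sum(lik * pri)
  post
}
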