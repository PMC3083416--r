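# shared fixture builders for the suite

# tiny genotype dataset with hand-set calls (copies of allele_b)
make_dataset <- function(calls, status = NULL, alleles = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); p <- ncol(calls)
  if (is.null(status)) status <- rep(c("case", "control"), length.out = n)
  if (is.null(alleles)) alleles <- matrix(rep(c("A", "G"), p), p, 2, byrow = TRUE)
  ids <- sprintf("ind%02d", seq_len(n))
  genotype_dataset(
    samples = data.frame(family_id = ids, individual_id = ids,
                         status = status, stringsAsFactors = FALSE),
    variants = data.frame(chrom = "1", snp_id = sprintf("rs%d", seq_len(p)),
                          bp = 100L * seq_len(p),
                          allele_a = alleles[, 1], allele_b = alleles[, 2],
                          stringsAsFactors = FALSE),
    calls = calls
  )
}

# well-separated archetype matrix for small clustering fixtures
blob_archetypes <- function() {
  rbind(a = c(3, 3, 3, 0, 0, 0, 0, 0, 0, 1, 1, 1),
        b = c(0, 0, 0, 3, 3, 3, 0, 0, 0, 1, 1, 1),
        c = c(0, 0, 0, 0, 0, 0, 3, 3, 3, 1, 1, 1),
        d = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 3, 3, 3))
}

blob_scores <- function(labels, noise_sd = 0.3, seed = 1) {
  arch <- blob_archetypes()
  set.seed(seed)
  n <- length(labels); p <- ncol(arch)
  X <- pmin(pmax(round(arch[labels, , drop = FALSE] +
                         matrix(rnorm(n * p, 0, noise_sd), n, p)), 0), 3)
  rownames(X) <- sprintf("case%03d", seq_len(n))
  X
}

# reference subtype assignment straight from simulation truth
truth_assignment <- function(truth) {
  asgn <- list(K = 4L, cluster = truth$subtype,
               names = c("Language-impaired", "Intermediate", "Moderate", "Mild"),
               sizes = tabulate(truth$subtype, 4L))
  asgn$case_names <- stats::setNames(asgn$names[asgn$cluster],
                                     names(asgn$cluster))
  class(asgn) <- "subtype_assignment"
  asgn
}
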