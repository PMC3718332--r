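# Core-genome divergence, NJ trees, molecular-clock dating.

test_that("pairwise divergence follows its definitions", {
  aln <- c(a = "ACGTACGTAC", b = "ACGTACGTAC")
  expect_equal(pairwise_divergence(aln)["a", "b"], 0)
  # exactly 10 mismatches over 1000 compared columns -> raw 0.01
  s <- rand_dna(1000, 501)
  s2 <- mutate_dna(s, 1:10, seed = 502)
  d <- pairwise_divergence(c(a = s, b = s2))
  expect_equal(d["a", "b"], 0.01)
  # gap columns are excluded pairwise
  d2 <- pairwise_divergence(c(a = "AC-TA", b = "ACGTA"))
  expect_equal(d2["a", "b"], 0)
  # Jukes-Cantor blows up at p >= 0.75
  x <- strrep("A", 100); y <- strrep("C", 100)
  expect_true(is.na(pairwise_divergence(c(a = x, b = y),
                                        "jukes_cantor")["a", "b"]))
  jc <- pairwise_divergence(c(a = s, b = s2), "jukes_cantor")
  expect_equal(jc["a", "b"], -0.75 * log(1 - 4 * 0.01 / 3))
})

# Exhaustive 4-taxon topology oracle: least-squares fit of the three
# unrooted quartet topologies to an additive distance matrix.
quartet_oracle <- function(d) {
  taxa <- rownames(d)
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  ss <- vapply(splits, function(pair) {
    a <- taxa[pair[1]]; b <- taxa[pair[2]]
    cd <- setdiff(taxa, c(a, b))
    # four-point condition residual for split ab|cd
    abs((d[a, cd[1]] + d[b, cd[2]]) - (d[a, cd[2]] + d[b, cd[1]]))
  }, 0)
  splits[[which.min(ss)]]
}

test_that("NJ recovers the generating quartet; 3 taxa give the star", {
  # additive distances on ((A,B),(C,D)) with internal branch 0.05
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  bl <- c(A = 0.01, B = 0.02, C = 0.015, D = 0.03)
  for (i in LETTERS[1:4]) for (j in LETTERS[1:4]) {
    if (i == j) next
    extra <- if (length(intersect(c(i, j), c("A", "B"))) == 1) 0.05 else 0
    d[i, j] <- bl[i] + bl[j] + extra
  }
  tr <- build_nj_tree(d, bootstrap = 0)
  split_ab <- quartet_oracle(d)
  expect_equal(sort(rownames(d)[split_ab]), c("A", "B"))
  # the unrooted NJ tree contains the split AB|CD
  pp <- ape::prop.part(tr)
  expect_true(any(vapply(pp, function(x) {
    tips <- tr$tip.label[x]
    setequal(tips, c("A", "B")) || setequal(tips, c("C", "D"))
  }, TRUE)))
  expect_error(build_nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "non-symmetric")
  d3 <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr3 <- build_nj_tree(d3, bootstrap = 0)
  expect_equal(ape::Ntip(tr3), 3)
})

test_that("bootstrap supports are reproducible and high on clean data", {
  sim <- cached("phylo_trio", {
    bg <- generate_background(50000, 0.35, seed = 505)
    evolve_strains(bg, "((LAL:60000,HVE:60000):400000,REY:460000,OUT:900000);",
                   seed = 506)
  })
  seqs <- vapply(sim$genomes, `[[`, "", "sequence")
  aln <- structure(list(genomes = names(seqs), sequences = seqs,
                        blocks = data.frame(family_id = "all", start = 1,
                                            end = nchar(seqs[1]))),
                   class = "CoreAlignment")
  d <- pairwise_divergence(aln)
  t1 <- build_nj_tree(d, alignment = aln, bootstrap = 30, seed = 9)
  t2 <- build_nj_tree(d, alignment = aln, bootstrap = 30, seed = 9)
  expect_equal(t1$node.label, t2$node.label)
  # planted sister pair is recovered
  pp <- ape::prop.part(t1)
  expect_true(any(vapply(pp, function(x) {
    tips <- t1$tip.label[x]
    setequal(tips, c("LAL", "HVE")) || setequal(tips, c("REY", "OUT"))
  }, TRUE)))
})

test_that("core alignment stacks single-copy families and drops discordant ones", {
  genomes <- c("g1", "g2")
  fam <- data.frame(family_id = c("F1", "F2"), n_members = 2L,
                    n_genomes = 2L, category = "ubiquitous",
                    multi_copy_single_genome = FALSE)
  fam$members <- list(
    data.frame(genome = genomes, protein = c("g1_a", "g2_a")),
    data.frame(genome = genomes, protein = c("g1_b", "g2_b")))
  fam$copy_counts <- list(c(g1 = 1L, g2 = 1L), c(g1 = 1L, g2 = 1L))
  s1 <- rand_dna(300, 510); s2 <- rand_dna(150, 511)
  gene_sequences <- list(g1 = c(g1_a = s1, g1_b = s2),
                         g2 = c(g2_a = s1, g2_b = s2))
  aln <- core_gene_alignment(fam, gene_sequences)
  expect_equal(nrow(aln$blocks), 2)
  expect_equal(unname(nchar(aln$sequences)), c(450, 450))
  expect_equal(pairwise_divergence(aln)["g1", "g2"], 0)
  # >20% length discordance drops the family
  gene_sequences$g2["g2_b"] <- rand_dna(100, 512)
  expect_message(aln2 <- core_gene_alignment(fam, gene_sequences),
                 "discordant")
  expect_equal(nrow(aln2$blocks), 1)
})

test_that("clock dating is the exact linear inversion t = d/(2 mu)", {
  expect_equal(date_divergence(0), 0)
  # the printed split time inverts to its implied divergence
  mu <- HYPERTHERMOPHILE_CLOCK_RATE
  d460 <- 2 * mu * 460000
  expect_equal(date_divergence(d460), 460000)
  expect_equal(date_divergence(4.287e-3), 459978.5, tolerance = 1e-4)
  expect_equal(date_divergence(2 * 0.004), 2 * date_divergence(0.004))
  expect_error(date_divergence(-0.1), "negative")
})

test_that("divergence and split time are recovered from evolved strains", {
  sim <- cached("phylo_pair", {
    bg <- generate_background(120000, 0.35, seed = 520)
    evolve_strains(bg, "(A:460000,B:460000);", seed = 521)
  })
  d <- pairwise_divergence(
    stats::setNames(vapply(sim$genomes, `[[`, "", "sequence"),
                    names(sim$genomes)))
  expected <- sim$expected_d["A", "B"]
  se <- sqrt(expected * (1 - expected) / 120000)
  expect_lt(abs(d["A", "B"] - expected), 3 * se)
  t_hat <- date_divergence(d["A", "B"])
  expect_lt(abs(t_hat - 460000) / 460000, 0.1)
})
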