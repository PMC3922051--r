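test_that("progressive alignment handles degenerate and identical inputs", {
  a <- "ACGTACGTAA"; b <- "ACGTACG"
  two <- progressive_msa(c(x = a, y = b))
  al <- global_align(a, b)
  expect_equal(unname(two["x"]), al$aligned_a)
  expect_equal(unname(two["y"]), al$aligned_b)

  five <- progressive_msa(structure(rep(strrep("ACGT", 10), 5),
                                    names = paste0("s", 1:5)))
  expect_false(any(grepl("-", five)))
  expect_equal(unique(nchar(five)), 40)
  expect_error(progressive_msa(c(x = "ACGT")), "at least 2")
})

test_that("alignment degapping recovers the inputs and beats a shuffled control", {
  set.seed(101)
  root <- rand_dna(60)
  seqs <- structure(vapply(1:6, function(i) mutate_seq(root, 0.1), ""),
                    names = paste0("s", 1:6))
  msa <- progressive_msa(seqs)
  expect_equal(unclass(gsub("-", "", msa)), seqs)
  expect_equal(length(unique(nchar(msa))), 1)

  # sum-of-pairs score is no worse than a column-shuffled control
  perm <- sample(nchar(msa[1]))
  shuffled <- vapply(msa, function(r) {
    paste(strsplit(r, "")[[1]][perm], collapse = "")
  }, "")
  expect_gte(sp_score(msa), sp_score(shuffled))
})

test_that("terminal gap-heavy columns are trimmed, interior columns kept", {
  rows <- c(a = "ACGTACGTAC----------",
            b = "ACGTACGTAC----------",
            c = "ACGTAC-TACGTACGTACGT")
  class(rows) <- "msa"
  tr <- trim_alignment(rows, max_gap_fraction = 0.5)
  expect_equal(unique(nchar(tr)), 10)
  expect_equal(unname(substr(tr["c"], 7, 7)), "-")  # interior gap untouched
  gap_free <- c(a = "ACGT", b = "ACGA")
  class(gap_free) <- "msa"
  expect_equal(unclass(trim_alignment(gap_free))[1:2], gap_free[1:2])
  all_gap <- c(a = "----", b = "AAAA")
  class(all_gap) <- "msa"
  expect_error(trim_alignment(all_gap, max_gap_fraction = 0.2), "every")
})

test_that("Jukes-Cantor distance matches the closed form and its oracle", {
  expect_equal(jc_distance(strrep("ACGT", 10), strrep("ACGT", 10)), 0)
  # short overlaps are flagged
  expect_true(attr(jc_distance("ACGTACGT", "ACGTACGT"), "unreliable"))
  # p = 0.1 over 100 sites
  a <- strrep("A", 100)
  b <- paste0(strrep("C", 10), strrep("A", 90))
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(jc_distance(a, b), 0.107326, tolerance = 1e-5)

  # random pairs match direct evaluation, and the matrix agrees with ape
  set.seed(103)
  root <- rand_dna(200)
  seqs <- structure(c(root, mutate_seq(root, 0.05), mutate_seq(root, 0.15),
                      mutate_seq(root, 0.3)), names = paste0("t", 1:4))
  msa <- progressive_msa(seqs)
  D <- jc_dist_matrix(msa)
  for (i in 1:3) for (j in (i + 1):4) {
    ai <- strsplit(msa[[i]], "")[[1]]; aj <- strsplit(msa[[j]], "")[[1]]
    sh <- ai != "-" & aj != "-"
    p <- sum(ai[sh] != aj[sh]) / sum(sh)
    expect_equal(D[i, j], -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
  }
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(unname(msa)), "")))
  rownames(bin) <- names(msa)
  Dape <- as.matrix(ape::dist.dna(bin, model = "JC69", pairwise.deletion = TRUE))
  expect_equal(unname(D), unname(Dape[names(msa), names(msa)]),
               tolerance = 1e-9, ignore_attr = TRUE)

  # saturation cap and monotonicity
  expect_equal(jc_distance(strrep("A", 50), strrep("C", 50)), 5.0)
  p <- seq(0.01, 0.7, by = 0.01)
  d <- -0.75 * log(1 - 4 * p / 3)
  expect_true(all(diff(d) > 0))
  expect_error(jc_distance("----", "AAAA"), "shared")
})

test_that("neighbor joining recovers additive trees exactly", {
  # 4 taxa from ((A:1,B:2):1,(C:3,D:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(D)
  expect_s3_class(tr, "phylo")
  path <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(path), unname(D), tolerance = 1e-9)
  # the (A,B) cherry exists
  part <- ape::prop.part(ape::unroot(tr))
  expect_true(any(vapply(part, function(p) {
    setequal(tr$tip.label[p], c("A", "B")) || setequal(tr$tip.label[p], c("C", "D"))
  }, logical(1))))

  # 3 taxa: closed-form three-point lengths
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(D3)
  path3 <- ape::cophenetic.phylo(t3)[rownames(D3), colnames(D3)]
  expect_equal(unname(path3), unname(D3), tolerance = 1e-12)

  # 7 random additive matrices: path metric reproduced below 1e-9
  set.seed(107)
  for (i in 1:7) {
    rt <- ape::rtree(sample(5:12, 1))
    Dr <- ape::cophenetic.phylo(rt)
    out <- nj_tree(Dr)
    Dout <- ape::cophenetic.phylo(out)[rownames(Dr), colnames(Dr)]
    expect_lt(max(abs(Dout - Dr)), 1e-9)
    # independent implementation agrees on the topology
    ref <- ape::nj(as.dist(Dr))
    expect_equal(ape::dist.topo(ape::unroot(out), ape::unroot(ref)), 0,
                 ignore_attr = TRUE)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
})

test_that("bootstrap supports behave as bipartition frequencies", {
  p <- generate_reference_panel(2, 3, 500, 0.30, 0.01, seed = 4)
  seqs <- structure(p$sequence, names = p$id)
  msa <- progressive_msa(seqs)
  tr <- bootstrap_support(msa, n_replicates = 100, seed = 9)
  sup <- as.numeric(tr$node.label)
  expect_true(all(sup >= 0 & sup <= 1))
  # the deep split between the two kingdoms is overwhelmingly supported
  desc <- phangorn::Descendants(tr, type = "tips")
  ntip <- length(tr$tip.label)
  split_sup <- NA
  for (nd in (ntip + 1):(ntip + tr$Nnode)) {
    tips <- tr$tip.label[desc[[nd]]]
    kg <- unique(sub("_r\\d+$", "", tips))
    if (length(tips) == 3 && length(kg) == 1) split_sup <- max(split_sup, sup[nd - ntip], na.rm = TRUE)
  }
  expect_gte(split_sup, 0.95)

  # single replicate: supports are 0 or 1
  tr1 <- bootstrap_support(msa, n_replicates = 1, seed = 2)
  expect_true(all(as.numeric(tr1$node.label) %in% c(0, 1)))

  # supports are invariant to input row order
  perm <- c(4, 1, 6, 2, 5, 3)
  msa2 <- msa[perm]
  class(msa2) <- "msa"
  tr2 <- bootstrap_support(msa2, n_replicates = 100, seed = 9)
  sup_of <- function(t) {
    d <- phangorn::Descendants(t, type = "tips")
    s <- as.numeric(t$node.label)
    nt <- length(t$tip.label)
    keys <- vapply((nt + 1):(nt + t$Nnode), function(nd) {
      paste(sort(t$tip.label[d[[nd]]]), collapse = ",")
    }, "")
    structure(s, names = keys)
  }
  s1 <- sup_of(tr); s2 <- sup_of(tr2)
  common <- intersect(names(s1), names(s2))
  expect_gt(length(common), 2)
  expect_equal(s1[common], s2[common])
  expect_error(bootstrap_support(msa, n_replicates = 0), "n_replicates")
})

test_that("clade assignment recovers planted kingdoms and flags aliens", {
  p <- generate_reference_panel(5, 4, 400, 0.30, 0.05, seed = 11)
  mk <- make_queries(p, 12, 0.02, seed = 12)
  cls <- classify_representatives(mk$queries, p, n_replicates = 60, seed = 13)
  expect_gte(label_accuracy(cls$assignments, mk$truth), 0.8)

  # an exact copy of a reference lands in that reference's kingdom
  copy <- structure(p$sequence[7], names = "COPY")
  cls2 <- classify_representatives(copy, p, n_replicates = 60, seed = 14)
  lab <- cls2$assignments$label[cls2$assignments$query == "COPY"]
  expect_equal(lab, p$kingdom[7])

  # unrelated random queries are NOVEL
  set.seed(15)
  alien <- structure(vapply(1:3, function(i) rand_dna(400), ""),
                     names = paste0("R", 1:3))
  cls3 <- classify_representatives(alien, p, n_replicates = 40, seed = 16)
  expect_true(all(cls3$assignments$label == "NOVEL"))
  expect_error(assign_clades(cls3$tree, c(nope = "X")), "no reference")
})

test_that("clade abundance matrix tallies read percentages per sample", {
  counts <- matrix(c(30, 0,
                     70, 50,
                     0, 50), nrow = 3, byrow = TRUE,
                   dimnames = list(c("o1", "o2", "o3"), c("S1", "S2")))
  tab <- structure(list(level = 0.2, counts = counts,
                        otus = data.frame(otu_id = rownames(counts)),
                        members = list()), class = "otu_table")
  asg <- data.frame(query = c("o1", "o2", "o3"),
                    label = c("X", "Y", "Y"), stringsAsFactors = FALSE)
  cam <- clade_abundance_matrix(asg, tab)
  expect_equal(unname(rowSums(cam)), c(100, 100))
  expect_equal(cam["S1", "X"], 30)
  expect_equal(cam["S1", "Y"], 70)
  expect_equal(cam["S2", "X"], 0)
  expect_equal(cam["S2", "Y"], 100)

  # single clade: row of 100
  asg1 <- data.frame(query = c("o1", "o2", "o3"), label = "Z",
                     stringsAsFactors = FALSE)
  expect_true(all(clade_abundance_matrix(asg1, tab) == 100))

  # unassigned OTU is an error naming the id
  expect_error(clade_abundance_matrix(asg[1:2, ], tab), "o3")

  # random fixtures: brute-force tally
  set.seed(17)
  for (i in 1:10) {
    cnt <- matrix(rpois(12, 5), 4, 3,
                  dimnames = list(paste0("u", 1:4), paste0("s", 1:3)))
    cnt[1, ] <- cnt[1, ] + 1   # keep every sample populated
    tb <- structure(list(level = 0.2, counts = cnt,
                         otus = data.frame(otu_id = rownames(cnt)),
                         members = list()), class = "otu_table")
    lab <- sample(c("A", "B"), 4, replace = TRUE)
    ag <- data.frame(query = rownames(cnt), label = lab, stringsAsFactors = FALSE)
    cam2 <- clade_abundance_matrix(ag, tb)
    for (s in colnames(cnt)) {
      for (l in unique(lab)) {
        expect_equal(cam2[s, l],
                     100 * sum(cnt[lab == l, s]) / sum(cnt[, s]))
      }
    }
  }
})
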