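expectedSplitSizes <- function(n) {
  base <- c(n %/% 5L * 3L, n %/% 5L, n %/% 5L)
  rem <- n %% 5L
  base + tabulate(rep_len(1:3, rem), nbins = 3L)
}

test_that("positives are partitioned 3:1:1, disjoint and exhaustive", {
  for (n in c(5L, 7L, 10L, 23L, 100L, 999L, 1000L)) {
    net <- PriorNetwork(data.frame(from = "TF1", to = paste0("T", seq_len(n))))
    sp <- splitPositives(net, seed = 42L)
    sizes <- splitSizes(sp)[1:3]
    expect_equal(unname(sizes), expectedSplitSizes(n))
    keys <- c(paste(sp@trainPos$from, sp@trainPos$to),
              paste(sp@valPos$from, sp@valPos$to),
              paste(sp@testPos$from, sp@testPos$to))
    expect_equal(sort(keys),
                 sort(paste(edges(net)$from, edges(net)$to)))
    expect_false(anyDuplicated(keys) > 0)
  }
  expect_equal(unname(expectedSplitSizes(10L)), c(6L, 2L, 2L))
  expect_equal(unname(expectedSplitSizes(5L)), c(3L, 1L, 1L))
})

test_that("splits are deterministic in the seed and need >= 5 positives", {
  net <- randomNet(4, 20, 0.25, seed = 2)
  a <- splitPositives(net, seed = 7L)
  b <- splitPositives(net, seed = 7L)
  expect_identical(a@trainPos, b@trainPos)
  expect_identical(a@testPos, b@testPos)
  c <- splitPositives(net, seed = 8L)
  expect_false(identical(a@trainPos, c@trainPos))
  small <- tinyNet(data.frame(from = c("A", "A", "B", "B"),
                              to = c("B", "C", "C", "D")))
  expect_error(splitPositives(small), "at least 5")
})

test_that("hard negatives share sources with positives and avoid edges", {
  # exhaustively enumerable pool: the only candidate is (A, C)
  net <- tinyNet(data.frame(from = "A", to = "B"), genes = c("A", "B", "C"),
                 tfs = "A")
  neg <- sampleHardNegatives(data.frame(from = "A", to = "B"), net,
                             ratio = 1, seed = 1L)
  expect_equal(neg, data.frame(from = "A", to = "C"))
  # across many seeded draws on a random net: sources mirror positives,
  # never a true edge, never a duplicate, deterministic under seed
  net <- randomNet(5, 60, 0.08, seed = 3)
  pos <- edges(net)
  outDeg <- table(pos$from)
  expect_true(all(2 * outDeg < length(genes(net)) - 1L))
  edgeKeys <- paste(pos$from, pos$to)
  for (seed in 1:20) {
    neg <- sampleHardNegatives(pos, net, ratio = 1, seed = seed)
    negKeys <- paste(neg$from, neg$to)
    expect_length(intersect(negKeys, edgeKeys), 0)
    expect_false(anyDuplicated(negKeys) > 0)
    expect_true(all(neg$from %in% tfSet(net)))
    # restricted pool stays nonempty, so sources mirror the positives
    expect_identical(sort(neg$from), sort(pos$from))
    expect_identical(sampleHardNegatives(pos, net, ratio = 1, seed = seed),
                     neg)
  }
})

test_that("exhausted pools fall back and finally warn", {
  # TF A has genes {B, C}; both are its targets -> restricted pool empty,
  # fallback must draw from TF B's pool instead
  net <- tinyNet(data.frame(from = c("A", "A"), to = c("B", "C")),
                 genes = c("A", "B", "C"), tfs = c("A", "B"))
  neg <- sampleHardNegatives(data.frame(from = "A", to = "B"), net,
                             ratio = 1, seed = 2L)
  expect_equal(nrow(neg), 1L)
  expect_true(neg$from == "B")
  # entire pool exhausted -> warning and short sample
  netFull <- tinyNet(data.frame(from = c("A", "A"), to = c("B", "C")),
                     genes = c("A", "B", "C"), tfs = "A")
  expect_warning(
    out <- sampleHardNegatives(edges(netFull), netFull, ratio = 1, seed = 3L),
    "exhausted")
  expect_equal(nrow(out), 0L)
})

test_that("density-matched negative counts follow (1 - rho)/rho", {
  # rho = 0.5: 10 TF->gene pairs possible, 5 edges
  g <- c(paste0("TF", 1:2), paste0("T", 1:4))
  e5 <- data.frame(from = c("TF1", "TF1", "TF1", "TF2", "TF2"),
                   to = c("T1", "T2", "T3", "T1", "T2"))
  net5 <- PriorNetwork(e5, genes = g, tfSet = c("TF1", "TF2"))
  expect_equal(networkDensity(net5), 0.5)
  testPos <- e5[1:2, ]
  neg <- densityMatchedTestNegatives(testPos, net5, seed = 1L)
  expect_equal(nrow(neg), 2L)   # |testPos| * (1 - 0.5)/0.5
  expect_true(all(neg$from %in% tfSet(net5)))
  # rho = 0.2 -> 4 negatives per positive
  g2 <- c("TF1", paste0("T", 1:20))
  e4 <- data.frame(from = "TF1", to = paste0("T", 1:4))
  net4 <- PriorNetwork(e4, genes = g2, tfSet = "TF1")
  expect_equal(networkDensity(net4), 0.2)
  neg4 <- densityMatchedTestNegatives(e4[1, ], net4, seed = 1L)
  expect_equal(nrow(neg4), 4L)
  expect_length(intersect(paste(neg4$from, neg4$to),
                          paste(e4$from, e4$to)), 0)
})

test_that("makeEdgeSplit compartments are mutually disjoint and labeled", {
  net <- randomNet(5, 30, 0.15, seed = 6)
  sp <- makeEdgeSplit(net, seed = 9L)
  expect_true(validObject(sp))
  s <- splitSizes(sp)
  expect_equal(unname(s[1:3]), expectedSplitSizes(nrow(edges(net))))
  expect_equal(s[["trainNeg"]], s[["trainPos"]])
  # negatives all have TF sources and are not edges
  allNeg <- rbind(sp@trainNeg, sp@valNeg, sp@testNeg)
  expect_true(all(allNeg$from %in% tfSet(net)))
  expect_length(intersect(paste(allNeg$from, allNeg$to),
                          paste(edges(net)$from, edges(net)$to)), 0)
})
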