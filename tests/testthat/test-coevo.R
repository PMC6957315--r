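ann_all <- function(n, anchors = seq_len(n), buried = integer(),
                    vestibule = integer()) {
  exposure <- rep("lipid_facing", n)
  exposure[buried] <- "buried"
  exposure[vestibule] <- "vestibule"
  data.frame(residue = seq_len(n), exposure = exposure,
             hbond_anchor = seq_len(n) %in% anchors)
}

test_that("sequence-separation and probability boundaries are literal", {
  tab <- data.frame(i = c(10, 10, 10), j = c(17, 18, 30),
                    score = 1, probability = c(0.9, 0.9, 0.5))
  out <- filter_pairs(tab, ann_all(40))
  # |i-j| = 7 excluded, 8 eligible; probability exactly 0.5 excluded
  expect_equal(nrow(out), 1)
  expect_equal(out$j, 18)
})

test_that("a hand-built six-pair table leaves exactly the hand-counted survivors", {
  tab <- data.frame(
    i = c(5, 5, 12, 30, 40, 50),
    j = c(20, 32, 25, 38, 70, 55),
    score = 1,
    probability = c(0.9, 0.8, 0.7, 0.9, 0.4, 0.95))
  # residue 25 buried; pair (30,38) has no anchor; (40,70) fails probability;
  # (50,55) fails separation -> survivors: (5,20), (5,32)
  ann <- ann_all(80, anchors = c(5, 20, 32, 12, 40, 70, 50, 55),
                 buried = 25)
  ann$hbond_anchor[ann$residue %in% c(30, 38)] <- FALSE
  out <- filter_pairs(tab, ann)
  expect_equal(nrow(out), 2)
  expect_setequal(paste(out$i, out$j), c("5 20", "5 32"))
})

test_that("unannotated residues in candidate pairs raise a listing error", {
  tab <- data.frame(i = 5, j = 20, score = 1, probability = 0.9)
  ann <- ann_all(10)
  expect_error(filter_pairs(tab, ann), "20")
})

test_that("clustering forms connected components deterministically", {
  pairs <- data.frame(i = c(5, 5, 20), j = c(20, 32, 40),
                      score = 1, probability = 0.9)
  cl <- cluster_pairs(pairs)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$residues, c(5, 20, 32, 40))
  # disjoint pairs form separate clusters
  cl2 <- cluster_pairs(data.frame(i = c(5, 60), j = c(20, 80),
                                  score = 1, probability = 0.9))
  expect_length(cl2, 2)
  expect_equal(cl2[[1]]$residues, c(5, 20))
  expect_equal(cl2[[2]]$residues, c(60, 80))
  # empty input, empty output
  expect_length(cluster_pairs(data.frame(i = integer(), j = integer())), 0)
  # independence of input order
  perm <- data.frame(i = c(20, 5, 5), j = c(40, 32, 20),
                     score = 1, probability = 0.9)
  clp <- cluster_pairs(perm)
  expect_equal(clp[[1]]$residues, cl[[1]]$residues)
})

test_that("clustering partitions the retained pairs", {
  set.seed(12)
  tab <- generate_coupling_table(120, list(c(8, 30, 52), c(70, 90),
                                           c(17, 40)), noise_pairs = 20,
                                 seed = 12)
  res <- coevo_clusters(tab, coupling_annotations(tab))
  n_pairs <- sum(vapply(res$clusters, function(cl) nrow(cl$pairs),
                        numeric(1)))
  expect_equal(n_pairs, nrow(res$retained))
  # every member residue appears in >= 1 member pair
  for (cl in res$clusters)
    expect_setequal(cl$residues, unique(c(cl$pairs$i, cl$pairs$j)))
})

test_that("planted clusters are recovered exactly end-to-end", {
  planted <- list(c(5, 20, 40), c(12, 33), c(60, 80, 100))
  tab <- generate_coupling_table(110, planted, noise_pairs = 25, seed = 9)
  res <- coevo_clusters(tab, coupling_annotations(tab))
  expect_length(res$clusters, 3)
  got <- lapply(res$clusters, `[[`, "residues")
  # clusters ordered by smallest member
  expect_equal(got[[1]], c(5, 20, 40))
  expect_equal(got[[2]], c(12, 33))
  expect_equal(got[[3]], c(60, 80, 100))
})

test_that("removing all anchors empties the output", {
  tab <- generate_coupling_table(60, list(c(5, 20, 40)), seed = 2)
  ann <- coupling_annotations(tab)
  ann$hbond_anchor <- FALSE
  expect_equal(nrow(filter_pairs(tab, ann)), 0)
  expect_length(coevo_clusters(tab, ann)$clusters, 0)
})

test_that("coupling tables round-trip through EVcouplings-style CSV", {
  tab <- generate_coupling_table(60, list(c(5, 20, 40)), noise_pairs = 4,
                                 seed = 3)
  path <- tempfile(fileext = ".csv")
  write_coupling_csv(tab, path)
  back <- read_coupling_csv(path)
  expect_equal(back$i, tab$i)
  expect_equal(back$probability, tab$probability, tolerance = 1e-12)
  bad <- tempfile(fileext = ".csv")
  write.csv(data.frame(i = 1, j = 1, score = 1, probability = 0.7), bad,
            row.names = FALSE)
  expect_error(read_coupling_csv(bad), "self-pairs")
})
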