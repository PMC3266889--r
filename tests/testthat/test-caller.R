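.mk_cluster <- function(id, direction, boundary, outer, family = "roo",
                        contig = "2L", n = 5L) {
  data.frame(cluster_id = id, contig = contig, direction = direction,
             family = family, order = "LTR", n_fragments = n,
             boundary = boundary, outer = outer,
             amin = pmin(boundary, outer) - 150L,
             amax = pmax(boundary, outer) + 150L,
             stringsAsFactors = FALSE)
}

test_that("anchors within the gap threshold form a single cluster", {
  set.seed(42)
  fr <- make_presence(c(1000L, 1100L, 1300L))
  cl <- cluster_directional(fr)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_fragments, 3L)
  expect_equal(cl$boundary, 1300L)      # max anchor for a forward cluster
  expect_equal(cl$outer, 1226L)         # start of the boundary read
})

test_that("clusters below the support minimum are discarded", {
  set.seed(42)
  fr <- make_presence(c(1000L, 1100L))
  expect_equal(nrow(cluster_directional(fr)), 0L)
  expect_equal(nrow(cluster_directional(fr[0, ])), 0L)
})

test_that("a gap of exactly the threshold splits the chain", {
  set.seed(42)
  fr <- make_presence(c(1000L, 1224L, 1449L))
  # 224 joins, 225 splits -> largest piece has 2 members -> nothing survives
  expect_equal(nrow(cluster_directional(fr)), 0L)
  fr2 <- make_presence(c(1000L, 1224L, 1448L))
  expect_equal(nrow(cluster_directional(fr2)), 1L)
})

test_that("fragments below the mapping-quality floor never enter", {
  set.seed(42)
  fr <- make_presence(c(1000L, 1050L, 1100L, 1150L))
  fr$mq <- c(15L, 14L, 15L, 15L)
  cl <- cluster_directional(fr)
  expect_equal(cl$n_fragments, 3L)
})

test_that("clustering matches the quadratic single-linkage oracle", {
  set.seed(42)
  n <- 10000L
  contig <- sample(c("2L", "2R"), n, replace = TRUE)
  direction <- sample(c("forward", "reverse"), n, replace = TRUE)
  family <- sample(sprintf("fam%d", 1:4), n, replace = TRUE)
  anchor <- sample.int(50000L, n, replace = TRUE)
  fwd <- direction == "forward"
  fr <- data.frame(qname = sprintf("q%05d", seq_len(n)), kind = "PRESENCE",
                   direction = direction, family = family, order = "LTR",
                   contig = contig,
                   g_start = ifelse(fwd, anchor - 74L, anchor),
                   g_end = ifelse(fwd, anchor, anchor + 74L),
                   anchor = anchor,
                   qualifying = ifelse(fwd, anchor - 74L, anchor + 73L),
                   mq = 20L, span_start = NA_integer_,
                   span_end = NA_integer_, stringsAsFactors = FALSE)
  cl <- cluster_directional(fr)
  asg <- attr(cl, "assignment")
  got <- lapply(split(asg$qname, asg$cluster_id), sort)
  got <- unname(got[order(vapply(got, `[`, character(1), 1L))])

  key <- paste(contig, direction, family)
  want <- list()
  for (k in unique(key)) {
    i <- which(key == k)
    mem <- oracle_cluster_members(anchor[i], contig[i], direction[i],
                                  family[i])
    want <- c(want, lapply(mem, function(m) sort(fr$qname[i][m])))
  }
  want <- unname(want[order(vapply(want, `[`, character(1), 1L))])
  expect_equal(got, want)
})

test_that("clustering is invariant to fragment order", {
  set.seed(42)
  fr <- make_presence(sample.int(20000L, 300L, replace = TRUE))
  cl1 <- cluster_directional(fr)
  cl2 <- cluster_directional(fr[sample.int(nrow(fr)), ])
  attr(cl1, "assignment") <- attr(cl2, "assignment") <- NULL
  expect_identical(cl1, cl2)
})

test_that("forward and reverse signals join within the masked-aware window", {
  g <- plain_genome()
  cl <- rbind(.mk_cluster(1L, "forward", boundary = 1074L, outer = 1000L),
              .mk_cluster(2L, "reverse", boundary = 1100L, outer = 1174L))
  calls <- join_forward_reverse(cl, g)
  expect_equal(calls$support, "FR")
  expect_equal(calls$join_distance, 174L)

  # too far apart: two single-direction calls
  cl2 <- rbind(.mk_cluster(1L, "forward", boundary = 1074L, outer = 1000L),
               .mk_cluster(2L, "reverse", boundary = 1526L, outer = 1600L))
  calls2 <- join_forward_reverse(cl2, g)
  expect_setequal(calls2$support, c("F", "R"))

  # different family never joins
  cl3 <- cl
  cl3$family[2] <- "jockey"
  expect_setequal(join_forward_reverse(cl3, g)$support, c("F", "R"))
})

test_that("masked sequence does not count toward the joining distance", {
  g <- Biostrings::DNAStringSet(c(`2L` = strrep("A", 200000L)))
  names(g) <- "2L"
  m <- mask_from_annotation(g, data.frame(contig = "2L", start = 1100,
                                          end = 1300))
  cl <- rbind(.mk_cluster(1L, "forward", boundary = 1074L, outer = 1000L),
              .mk_cluster(2L, "reverse", boundary = 1326L, outer = 1400L))
  # raw 400, minus 200 masked -> 200, inside the window
  calls <- join_forward_reverse(cl, m)
  expect_equal(calls$support, "FR")
  expect_equal(calls$join_distance, 200L)
})

test_that("each cluster joins at most one partner, nearest first", {
  g <- plain_genome()
  cl <- rbind(.mk_cluster(1L, "forward", boundary = 1074L, outer = 1000L),
              .mk_cluster(2L, "reverse", boundary = 1076L, outer = 1150L),
              .mk_cluster(3L, "reverse", boundary = 1126L, outer = 1200L))
  calls <- join_forward_reverse(cl, g)
  fr <- calls[calls$support == "FR", ]
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$rev_cluster, 2L)      # nearest partner wins
  expect_equal(sum(calls$support == "R"), 1L)
})

test_that("joining is symmetric under coordinate mirroring", {
  g <- plain_genome(200000L)
  L <- 200000L
  cl <- rbind(.mk_cluster(1L, "forward", boundary = 1074L, outer = 1000L),
              .mk_cluster(2L, "reverse", boundary = 1100L, outer = 1174L),
              .mk_cluster(3L, "forward", boundary = 5074L, outer = 5000L),
              .mk_cluster(4L, "reverse", boundary = 5400L, outer = 5480L))
  mirror <- cl
  mirror$direction <- ifelse(cl$direction == "forward", "reverse", "forward")
  mirror$boundary <- L - cl$boundary
  mirror$outer <- L - cl$outer
  tmp <- mirror$amin; mirror$amin <- L - cl$amax; mirror$amax <- L - tmp
  c1 <- join_forward_reverse(cl, g)
  c2 <- join_forward_reverse(mirror, g)
  expect_equal(sort(c1$support), sort(c2$support))
  expect_equal(sort(c1$join_distance[c1$support == "FR"]),
               sort(c2$join_distance[c2$support == "FR"]))
})

test_that("position estimates follow the midpoint / 26 bp rules", {
  g <- plain_genome()
  cl <- rbind(.mk_cluster(1L, "forward", boundary = 1000L, outer = 926L),
              .mk_cluster(2L, "reverse", boundary = 1100L, outer = 1174L))
  calls <- estimate_position(join_forward_reverse(cl, g))
  expect_equal(calls$position, 1050L)

  lone_f <- join_forward_reverse(.mk_cluster(1L, "forward", 1000L, 926L), g)
  expect_equal(estimate_position(lone_f)$position, 1026L)
  lone_r <- join_forward_reverse(.mk_cluster(1L, "reverse", 2000L, 2074L), g)
  expect_equal(estimate_position(lone_r)$position, 1974L)
})

test_that("reference matching is family-aware with an inclusive 300 bp bound", {
  g <- plain_genome()
  mk_call <- function(family, amin, amax) {
    cl <- .mk_cluster(1L, "forward", boundary = amax, outer = amin + 1L,
                      family = family)
    cl$amin <- amin; cl$amax <- amax
    estimate_position(join_forward_reverse(cl, g))
  }
  ann <- data.frame(contig = "2L", start = 2000L, end = 3000L,
                    family = "roo", id = "FBti0001")
  # supporting reads 120 bp from the span
  near <- match_to_reference_annotation(mk_call("roo", 1806L, 1880L), ann)
  expect_equal(near$known_novel, "known")
  expect_equal(near$reference_id, "FBti0001")
  # same position, different family
  other <- match_to_reference_annotation(mk_call("jockey", 1806L, 1880L),
                                         ann)
  expect_equal(other$known_novel, "novel")
  # exactly 300 bp away is still a match; 301 is not
  at300 <- match_to_reference_annotation(mk_call("roo", 1626L, 1700L), ann)
  expect_equal(at300$known_novel, "known")
  at301 <- match_to_reference_annotation(mk_call("roo", 1625L, 1699L), ann)
  expect_equal(at301$known_novel, "novel")
})

test_that("end-to-end calls are specific and partition by support", {
  sim <- small_sim()
  truth <- sim$pool$truth_insertions
  mid <- ifelse(truth$in_reference,
                (truth$span_start + truth$span_end) %/% 2L,
                truth$ref_position)
  # every call sits at a simulated insertion of the same family
  for (i in seq_len(nrow(sim$calls))) {
    d <- abs(mid - sim$calls$position[i])
    same <- tolower(truth$family) == tolower(sim$calls$family[i])
    expect_true(any(same & d < 1000))
  }
  # every simulated insertion with enough support is recovered
  expect_true(all(vapply(seq_len(nrow(truth)), function(j) {
    any(tolower(sim$calls$family) == tolower(truth$family[j]) &
          abs(sim$calls$position - mid[j]) < 1000)
  }, logical(1))))
  # support categories partition the calls
  expect_equal(sum(sim$calls$support == "FR") +
                 sum(sim$calls$support == "F") +
                 sum(sim$calls$support == "R"), nrow(sim$calls))
  # the known insertion is matched, the novel ones are not
  expect_equal(sort(unique(sim$calls$known_novel)), c("known", "novel"))
})
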