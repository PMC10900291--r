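test_that("topological lengths and their sum follow the index arithmetic", {
  s <- xlink_set(c(3, 4), c(50, 50), "BS3")
  expect_equal(topological_length(s), c(47, 46))
  expect_equal(sigma_L(s), 93)
  expect_equal(topological_length(s, "loop_size"), c(48, 47))
  expect_equal(sigma_L(xlink_set(integer(), integer())), 0)

  # additive over disjoint unions, invariant to order
  s1 <- xlink_set(c(1, 2), c(10, 30), "BS3")
  s2 <- xlink_set(5, 90, "BS3")
  expect_equal(sigma_L(s1) + sigma_L(s2),
               sigma_L(xlink_set(c(5, 1, 2), c(90, 10, 30), "BS3")))
  # invariant under a uniform renumbering offset
  expect_equal(sigma_L(xlink_set(c(101, 102), c(110, 130), "BS3")),
               sigma_L(s1))
})

test_that("the improvement-capacity rule is strict at 150", {
  mk <- function(sl) xlink_set(1, 1 + sl, "BS3")
  expect_equal(predict_improvement(mk(151))$class, "high-capacity")
  expect_equal(predict_improvement(mk(150))$class, "low-capacity")
  out <- predict_improvement(xlink_set(c(1, 10), c(100, 80), "BS3"))
  expect_equal(out$sigma_L, 169)
  expect_equal(out$n_links, 2)
  expect_equal(out$max_L, 99)
  expect_equal(out$class, "high-capacity")
})

test_that("cross-link sets enforce their invariants", {
  expect_error(xlink_set(5, 5, "BS3"), "self-link")
  expect_error(xlink_set(c(1, 2, 1), c(9, 8, 9), "BS3"), "duplicate")
  expect_error(xlink_set(1, 9, "BS3", confidence = 1.5), "confidence")
  # same pair under two reagents is two distinct links
  s <- xlink_set(c(1, 1), c(9, 9), c("BS3", "DSG"))
  expect_equal(nrow(s), 2)
})

test_that("pair finding respects specificity, distance and exposure", {
  # helix with lysines at both ends, alanine elsewhere: no Lys pair is
  # within reach of DSA (d_u = 7) but several are for BS3 (d_u = 12)
  aa <- rep("A", 20); aa[c(2, 5, 16, 19)] <- "K"
  h <- ideal_helix(20, aa = aa)
  rg <- reagent_presets()
  expo <- cg_exposure(h)
  dsa <- find_crosslinkable_pairs(h, rg$DSA, exposure = expo)
  bs3 <- find_crosslinkable_pairs(h, rg$BS3, exposure = expo)
  sc_d <- function(s) mapply(function(i, j) sc_distance(h, i, j), s$i, s$j)
  expect_true(all(sc_d(bs3) <= 12))
  if (nrow(dsa) > 0) expect_true(all(sc_d(dsa) <= 7))
  # DSA pairs are a subset of BS3 pairs (tighter d_u shrinks the set)
  key <- function(s) paste(s$i, s$j)
  expect_true(all(key(dsa) %in% key(bs3)))
  # tightening exposure shrinks the set further
  strict <- suppressMessages(
    find_crosslinkable_pairs(h, rg$BS3, exposure_threshold = 0.9,
                             exposure = expo))
  expect_true(all(key(strict) %in% key(bs3)))
  # all returned pairs are lysine pairs
  for (k in seq_len(nrow(bs3))) {
    expect_equal(h$aa[match(c(bs3$i[k], bs3$j[k]), h$resno)], c("K", "K"))
  }
  # no lysines at all: empty set
  none <- suppressMessages(
    find_crosslinkable_pairs(ideal_helix(12, aa = "A"), rg$DSA))
  expect_equal(nrow(none), 0)
})

test_that("a buried side chain is excluded from cross-linkable pairs", {
  # two parallel helices: interface side chains point inward and are
  # occluded, outward-facing ones stay exposed
  hb <- helix_bundle(12, sep = 7)
  expo <- cg_exposure(hb)
  # the most buried side chain is far less accessible than the most exposed
  expect_lt(min(expo), 0.5 * max(expo))
  buried <- which.min(expo)
  aa <- rep("A", 24); aa[buried] <- "K"
  exposed <- which.max(expo)
  aa[exposed] <- "K"
  hb$aa <- aa
  thr <- (expo[buried] + expo[exposed]) / 2
  pairs <- suppressMessages(find_crosslinkable_pairs(
    hb, reagent_presets()$BS3, exposure_threshold = thr, exposure = expo))
  expect_false(buried %in% c(pairs$i, pairs$j))
})

test_that("violation census counts excesses over each margin", {
  # straight stretched chain: Ca distance grows linearly with separation
  n <- 40
  ch <- suppressWarnings(cg_chain(
    seq_len(n), rep("K", n),
    ca = cbind(3.8 * (seq_len(n) - 1), 0, 0),
    sc = cbind(3.8 * (seq_len(n) - 1), 2, 0)))
  rg <- reagent_presets()
  span <- rg$BS3$max_ca_span                       # 12 + 2*6.4 = 24.8
  expect_equal(span, 24.8)
  # pick pairs: satisfied, excess ~7 (over 5 not 10), excess > 10
  sep_for <- function(target) round((span + target) / 3.8)
  s <- xlink_set(c(1, 1, 1), 1 + c(3, sep_for(7), sep_for(20)), "BS3")
  rep <- violation_report(ch, s)
  expect_equal(unname(rep$counts["n_total"]), 3L)
  expect_equal(unname(rep$counts["n_over_5"]), 2L)
  expect_equal(unname(rep$counts["n_over_10"]), 1L)
  expect_equal(rep$per_link$excess,
               rep$per_link$ca_distance - rep$per_link$max_length)
  # counts monotone non-increasing in the margin
  many <- violation_report(ch, s, margins = c(0, 2, 5, 10, 20, 50))
  expect_true(all(diff(unname(many$counts[-1])) <= 0))
  # an all-satisfied set reports zero
  ok <- violation_report(ch, xlink_set(c(1, 2), c(3, 6), "BS3"))
  expect_equal(unname(ok$counts["n_over_5"]), 0L)
  expect_equal(unname(ok$counts["n_over_10"]), 0L)
  # unresolvable links are excluded and flagged
  expect_warning(bad <- violation_report(ch, xlink_set(1, 99, "BS3")),
                 "unresolvable")
  expect_equal(unname(bad$counts["n_total"]), 0L)
  expect_equal(nrow(bad$unresolved), 1)
})

test_that("a link stretched 7 angstrom past max length is over-5 only", {
  rg <- reagent_presets()$DSA
  d_target <- rg$max_ca_span + 7
  ch <- suppressWarnings(cg_chain(
    1:2, c("K", "K"),
    ca = rbind(c(0, 0, 0), c(d_target, 0, 0)),
    sc = rbind(c(0, 2, 0), c(d_target, 2, 0))))
  rep <- violation_report(ch, xlink_set(1, 2, "DSA"))
  expect_equal(unname(rep$counts["n_over_5"]), 1L)
  expect_equal(unname(rep$counts["n_over_10"]), 0L)
})

test_that("cross-link tables round-trip through TSV with line diagnostics", {
  s <- xlink_set(c(4, 10, 33), c(50, 56, 41), c("DSA", "BS3", "SDA"),
                 confidence = c(1, 0.8, 0.5), protein_id = "toy")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_xlinks(s, path)
  got <- read_xlinks(path)
  expect_equal(got$i, s$i)
  expect_equal(got$j, s$j)
  expect_equal(got$reagent, s$reagent)
  expect_equal(got$confidence, s$confidence)
  expect_equal(attr(got, "protein_id"), "toy")

  # malformed rows are rejected with their line number
  writeLines(c("protein\tres_i\tres_j\treagent\tconfidence",
               "p\t3\t9\tBS3\t1.0",
               "p\t7\t7\tBS3\t1.0"), path)
  expect_error(read_xlinks(path), "line 3")

  # absent confidence column defaults to 1.0
  writeLines(c("protein\tres_i\tres_j\treagent", "p\t3\t9\tBS3"), path)
  expect_equal(read_xlinks(path)$confidence, 1.0)
})

test_that("reagent presets carry the documented upper bounds", {
  rg <- reagent_presets()
  expect_equal(vapply(rg[c("TATA", "SDA", "ABAS", "DSG", "DSA", "BS3", "SS")],
                      `[[`, numeric(1), "d_u"),
               c(TATA = 4, SDA = 5, ABAS = 6, DSG = 6, DSA = 7, BS3 = 12,
                 SS = 4.5))
  expect_true(all(vapply(rg, `[[`, numeric(1), "d_l") == 2.5))
})
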