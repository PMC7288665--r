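# Expression cross-reference: join, tissue counts, regulation overlap.

mkVerdicts <- function(psgs, others = character()) {
  data.frame(groupId = c(psgs, others),
             isPsgExclusive = c(rep(TRUE, length(psgs)),
                                rep(FALSE, length(others))))
}

mkExpr <- function(rows) {
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(gene_id = r[[1]], tissue = r[[2]],
               expressed = as.logical(r[[3]]),
               regulation = if (length(r) > 3) r[[4]] else NA_character_,
               contrast = if (length(r) > 4) r[[5]] else NA_character_,
               stringsAsFactors = FALSE)))
  df
}

test_that("the join is a left join on PSGs with unobserved flags", {
  v <- mkVerdicts(c("g1", "g2", "g3"), others = "g9")
  e <- mkExpr(list(list("g1", "midgut", TRUE),
                   list("g1", "fat_body", FALSE),
                   list("g2", "midgut", TRUE),
                   list("g9", "midgut", TRUE)))   # non-PSG: excluded
  j <- joinPSGExpression(v, e)
  expect_identical(sum(!j$unobserved), 3L)
  expect_identical(j$gene_id[j$unobserved], "g3")
  # row count equals the per-PSG expression-row tally plus unobserved
  expect_identical(nrow(j), 3L + 1L)
  # empty PSG set -> empty join
  expect_identical(nrow(joinPSGExpression(mkVerdicts(character()), e)),
                   0L)
  # duplicate keys are an input error
  dup <- mkExpr(list(list("g1", "midgut", TRUE),
                     list("g1", "midgut", FALSE)))
  expect_error(joinPSGExpression(v, dup), "duplicate")
  # synonym maps translate ids before joining
  syn <- data.frame(old_id = "x9", new_id = "g2")
  e2 <- mkExpr(list(list("x9", "midgut", TRUE)))
  j2 <- joinPSGExpression(v, e2, synonyms = syn)
  expect_identical(j2$gene_id[!j2$unobserved], "g2")
})

test_that("tissue counts: expression, exclusivity and conservation", {
  v <- mkVerdicts(sprintf("g%d", 1:5))
  e <- mkExpr(list(
    list("g1", "salivary_gland", TRUE),               # exclusive SG
    list("g2", "salivary_gland", TRUE),
    list("g2", "midgut", TRUE),                        # shared
    list("g3", "midgut", TRUE),                        # exclusive MG
    list("g4", "salivary_gland", FALSE),               # not expressed
    list("g4", "fat_body", TRUE)))                     # exclusive FB
  j <- joinPSGExpression(v, e)
  ct <- countByTissue(j, innovationOrgans = c("salivary_gland",
                                              "midgut"))
  pt <- ct$perTissue
  expect_identical(pt$expressed[pt$tissue == "salivary_gland"], 2L)
  expect_identical(pt$exclusive[pt$tissue == "salivary_gland"], 1L)
  expect_identical(pt$expressed[pt$tissue == "midgut"], 2L)
  expect_identical(pt$exclusive[pt$tissue == "midgut"], 1L)
  expect_identical(pt$exclusive[pt$tissue == "fat_body"], 1L)
  expect_identical(ct$nExpressedInInnovationOrgans, 3L)
  expect_identical(ct$nPsgs, 5L)
  expect_identical(ct$nExpressedAnywhere, 4L)
  expect_identical(ct$nUnobserved, 1L)                 # g5
  # conservation: exclusive <= expressed per tissue; totals partition
  expect_true(all(pt$exclusive <= pt$expressed))
  expect_lte(sum(pt$exclusive), ct$nPsgs)
  # a gene expressed in all tissues counts everywhere, exclusively
  # nowhere
  e2 <- mkExpr(lapply(c("salivary_gland", "midgut", "fat_body"),
                      function(ts) list("g1", ts, TRUE)))
  ct2 <- countByTissue(joinPSGExpression(mkVerdicts("g1"), e2))
  expect_true(all(ct2$perTissue$expressed == 1L))
  expect_true(all(ct2$perTissue$exclusive == 0L))
})

test_that("regulation overlap recovers a planted 5-up/1-down
          intersection across contrasts", {
  psgs <- sprintf("g%02d", 1:20)
  v <- mkVerdicts(psgs)
  rows <- list()
  # five genes up in both contrasts, one down in both
  for (g in psgs[1:5]) {
    rows <- c(rows, list(list(g, "midgut", TRUE, "up", "apo"),
                         list(g, "midgut", TRUE, "up", "inf")))
  }
  rows <- c(rows, list(list("g06", "midgut", TRUE, "down", "apo"),
                       list("g06", "midgut", TRUE, "down", "inf")))
  # noise: discordant statuses
  rows <- c(rows, list(list("g07", "midgut", TRUE, "up", "apo"),
                       list("g07", "midgut", TRUE, "down", "inf"),
                       list("g08", "midgut", TRUE, "up", "apo")))
  e <- mkExpr(rows)
  j <- joinPSGExpression(v, e)
  both <- regulationOverlap(j, c("apo", "inf"))
  expect_identical(both$count[both$regulation == "up"], 5L)
  expect_identical(both$count[both$regulation == "down"], 1L)
  expect_identical(both$count[both$regulation == "unchanged"], 0L)
  # single-contrast counts equal column tallies
  one <- regulationOverlap(j, "apo")
  expect_identical(one$count[one$regulation == "up"], 7L)
  expect_identical(one$count[one$regulation == "down"], 1L)
  # all-NA regulation -> zero everywhere
  eNA <- mkExpr(list(list("g01", "midgut", TRUE, NA, "apo")))
  allNA <- regulationOverlap(joinPSGExpression(v, eNA), "apo")
  expect_true(all(allNA$count == 0L))
  expect_error(regulationOverlap(j, "nope"), "unknown")
})

test_that("re-joining the join's own expression rows leaves the
          summaries unchanged (idempotence)", {
  v <- mkVerdicts(sprintf("g%d", 1:4))
  e <- mkExpr(list(list("g1", "midgut", TRUE),
                   list("g2", "midgut", TRUE),
                   list("g2", "fat_body", TRUE),
                   list("g3", "fat_body", FALSE)))
  j <- joinPSGExpression(v, e)
  again <- joinPSGExpression(
    v, j[!j$unobserved,
         c("gene_id", "tissue", "expressed", "regulation", "contrast")])
  expect_identical(countByTissue(again)$perTissue,
                   countByTissue(j)$perTissue)
  expect_identical(countByTissue(again)$nExpressedAnywhere,
                   countByTissue(j)$nExpressedAnywhere)
})
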