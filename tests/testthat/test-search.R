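test_that("runQuery fans out, groups deterministically, and isolates failures", {
  reg <- makeMockRegistry(fixtureSpec(seed = 2L), counts = c(2, 2))
  q <- newQuery(keywords = "record", sources = listSources(reg))
  tab <- runQuery(q, reg)
  expect_gte(length(resultGroups(tab)), 2L)
  expect_identical(sum(vapply(tab@groups, length, integer(1))), 4L)
  expect_identical(resultGroups(tab), sort(resultGroups(tab)))

  tab2 <- runQuery(q, reg)
  expect_identical(tab@groups, tab2@groups)        # deterministic

  regF <- makeMockRegistry(fixtureSpec(seed = 2L), counts = c(2, 1, 5),
                           faultIndex = 2L)
  tabF <- runQuery(newQuery(keywords = "record", sources = listSources(regF)),
                   regF)
  expect_identical(unname(sourceStatus(tabF)["mock2"]), "failed")
  expect_identical(unname(sourceStatus(tabF)[c("mock1", "mock3")]),
                   c("ok", "ok"))
  regOk <- makeMockRegistry(fixtureSpec(seed = 2L), counts = c(2, 1, 5))
  tabOk <- runQuery(newQuery(keywords = "record",
                             sources = listSources(regOk)), regOk)
  keep <- grep("^mock[13]", resultGroups(tabOk), value = TRUE)
  expect_identical(tabF@groups[keep], tabOk@groups[keep])

  expect_error(runQuery(newQuery("x", sources = "ghost"), reg),
               class = "atk_config")
  expect_error(newQuery(character(0), NULL, "mock1"))
})

test_that("the record multiset equals the union of ok sources (property)", {
  for (s in 1:10) {
    set.seed(900 + s)
    counts <- sample(0:5, 4, replace = TRUE)
    fault <- sample(0:4, 1)
    reg <- makeMockRegistry(fixtureSpec(seed = 900L + s), counts = counts,
                            faultIndex = fault)
    q <- newQuery(keywords = "record", sources = listSources(reg))
    tab <- runQuery(q, reg)
    got <- sort(unname(vapply(unlist(tab@groups), function(r)
      as.numeric(r@annotations$id), numeric(1))))
    want <- numeric(0)
    for (nm in listSources(reg)) {
      if (identical(unname(sourceStatus(tab)[nm]), "ok")) {
        recs <- get(nm, envir = reg)@execute(q)
        want <- c(want, vapply(recs, function(r)
          as.numeric(r@annotations$id), numeric(1)))
      }
    }
    expect_identical(got, sort(want))
  }
})

test_that("keyword/term routing respects declared search types", {
  d <- withr::local_tempdir()
  tsv <- file.path(d, "genes.tsv")
  write.table(data.frame(gene = c("lcn2", "gfap", "lcn2"),
                         structure = c("putamen", "cortex", "cortex")),
              tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  reg <- sourceRegistry()
  registerSource(reg, tableSource(tsv, name = "genes"))
  registerSource(reg, mockLiteratureSource(list(
    resultRecord("lit", "Publication", list(title = "lcn2 in putamen")),
    resultRecord("lit", "Publication", list(title = "unrelated"))),
    name = "lit"))

  # keyword-only query: term-only source is skipped with a status note
  qk <- newQuery(keywords = "lcn2", sources = c("genes", "lit"))
  tk <- runQuery(qk, reg)
  expect_identical(unname(sourceStatus(tk)["genes"]), "skipped")
  expect_match(tk@messages[["genes"]], "unsupported search type")
  expect_identical(length(groupRecords(tk, "lit/Publication")), 1L)

  # term query hits the table source only
  qt <- newQuery(terms = c(gene = "lcn2"), sources = c("genes", "lit"))
  tt <- runQuery(qt, reg)
  expect_identical(unname(sourceStatus(tt)["lit"]), "skipped")
  rows <- groupRecords(tt, "genes/Tabular")
  expect_length(rows, 2L)
  expect_true(all(vapply(rows, function(r)
    identical(r@annotations$gene, "lcn2"), logical(1))))
})

test_that("table view operations preserve content and sort stably", {
  recs <- list(
    resultRecord("s", "T", list(name = "b", score = 3, tie = 1)),
    resultRecord("s", "T", list(name = "a", score = 1, tie = 1)),
    resultRecord("s", "T", list(name = "c", tie = 1)),          # no score
    resultRecord("s", "T", list(name = "d", score = 2, tie = 1)))
  reg <- sourceRegistry()
  registerSource(reg, dataSource("s", "keyword", "T",
                                 function(q) recs))
  tab <- runQuery(newQuery("x", sources = "s"), reg)
  g <- "s/T"

  srt <- sortBy(tab, g, "score")
  expect_identical(vapply(groupRecords(srt, g), function(r)
    r@annotations$name, character(1)), c("a", "d", "b", "c"))  # missing last
  dec <- sortBy(tab, g, "score", decreasing = TRUE)
  expect_identical(vapply(groupRecords(dec, g), function(r)
    r@annotations$name, character(1)), c("b", "d", "a", "c"))

  # stable: equal keys keep prior relative order (reference: order())
  ties <- sortBy(tab, g, "tie")
  expect_identical(vapply(groupRecords(ties, g), function(r)
    r@annotations$name, character(1)), c("b", "a", "c", "d"))

  # record multiset untouched by any view op
  ops <- reorderColumns(setColumnVisible(srt, g, "score", FALSE), g,
                        c("tie", "score", "name"))
  ops <- setGroupExpanded(ops, g, FALSE)
  expect_setequal(vapply(groupRecords(ops, g), function(r)
    r@annotations$name, character(1)), c("a", "b", "c", "d"))
  expect_identical(ops@columnState[[g]]$visible, c("tie", "name"))
  expect_false(ops@columnState[[g]]$expanded)

  # hide then show restores the order position
  hs <- setColumnVisible(setColumnVisible(tab, g, "score", FALSE),
                         g, "score", TRUE)
  expect_identical(hs@columnState[[g]]$visible,
                   tab@columnState[[g]]$visible)
  expect_error(sortBy(tab, g, "nope"), class = "atk_key")
  expect_error(sortBy(tab, "x/y", "score"), class = "atk_key")
})

test_that("the cart keeps FIFO order, flags duplicates, and serializes", {
  r1 <- resultRecord("s", "T", list(name = "one"))
  r2 <- resultRecord("s", "T", list(name = "two"))
  r3 <- resultRecord("s", "T", list(name = "three"))
  cart <- cartAdd(cartAdd(cartAdd(newCart(), r1), r2), r3)
  expect_length(cartItems(cart), 3L)
  cart2 <- cartRemove(cart, 2)
  expect_identical(vapply(cartItems(cart2), function(r) r@annotations$name,
                          character(1)), c("one", "three"))
  expect_error(cartRemove(cart2, 9), class = "atk_bounds")
  expect_length(cartItems(newCart()), 0L)

  dup <- cartAdd(cartAdd(newCart(), r1), r1)
  expect_length(cartItems(dup), 2L)
  expect_identical(dup@duplicate, c(FALSE, TRUE))

  f <- withr::local_tempfile(fileext = ".json")
  saveCart(cart, f)
  loaded <- loadCart(f)
  expect_identical(vapply(cartItems(loaded), function(r) r@annotations$name,
                          character(1)), c("one", "two", "three"))
})

test_that("the directory image source matches keywords against names and sidecars", {
  d <- withr::local_tempdir()
  for (nm in c("putamen_01.png", "putamen_02.png", "cortex_01.png",
               "misc_a.png", "misc_b.png")) {
    png::writePNG(matrix(runif(4), 2, 2), file.path(d, nm))
  }
  writeLines("gene: lcn2", file.path(d, "misc_a.png.txt"))
  src <- directoryImageSource(d, name = "imgs")
  reg <- sourceRegistry()
  registerSource(reg, src)

  tab <- runQuery(newQuery("putamen", sources = "imgs"), reg)
  recs <- groupRecords(tab, "imgs/2D Image")
  expect_length(recs, 2L)
  expect_identical(recs[[1]]@dataType, "2D Image")
  expect_true(file.exists(recs[[1]]@payloadRef))

  viaSidecar <- runQuery(newQuery("lcn2", sources = "imgs"), reg)
  expect_identical(vapply(groupRecords(viaSidecar, "imgs/2D Image"),
                          function(r) r@annotations$file, character(1)),
                   "misc_a.png")
  # AND semantics across keywords
  both <- runQuery(newQuery(c("misc", "lcn2"), sources = "imgs"), reg)
  expect_length(groupRecords(both, "imgs/2D Image"), 1L)
  expect_error(directoryImageSource(file.path(d, "nope")),
               class = "atk_not_found")
})

test_that("queryFromAtlas turns selections into keywords and locations into terms", {
  q <- queryFromAtlas(selection = "putamen", sources = "aba")
  expect_identical(queryKeywords(q), "putamen")

  q2 <- queryFromAtlas(selection = "putamen", sources = "aba",
                       extraKeywords = "lcn2")
  expect_setequal(queryKeywords(q2), c("putamen", "lcn2"))

  q3 <- queryFromAtlas(location = c(2, 3, 4), sources = "aba")
  expect_identical(queryTerms(q3)$field, "location")
  expect_identical(queryTerms(q3)$value, "2.0,3.0,4.0")

  v <- imageVolume(array(0, c(8, 8, 8)), voxelSize = c(0.5, 0.5, 2),
                   origin = c(-5, 0, 2))
  q4 <- queryFromAtlas(location = voxelToWorld(v, c(5, 1, 2)),
                       sources = "aba")
  expect_identical(queryTerms(q4)$value, "-3.0,0.0,4.0")
  expect_error(queryFromAtlas(sources = "aba"), class = "atk_validation")
})
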