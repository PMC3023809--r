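brainSet <- function() {
  labelSet(data.frame(
    id = c(1L, 2L, 4L, 5L, 9L, 3L, 6L),
    abbrev = c("Br", "FB", "Ctx", "Amy", "DMH", "HB", "Pons"),
    name = c("Brain", "Forebrain", "Cerebral cortex", "Amygdala",
             "Dorsomedial nucleus of the hypothalamus", "Hindbrain", "Pons"),
    r = c(255L, 200L, 150L, 100L, 50L, 25L, 12L),
    g = c(0L, 40L, 80L, 120L, 160L, 200L, 240L),
    b = c(0L, 30L, 60L, 90L, 120L, 150L, 180L),
    parent = c(NA, 1L, 2L, 2L, 2L, 1L, 3L)), "anatomic")
}

test_that("ILF write/parse round-trips structure, colors and child order", {
  ls <- brainSet()
  f <- withr::local_tempfile(fileext = ".ilf")
  writeIlf(ls, f)
  ls2 <- parseIlf(f)
  expect_identical(labelNodes(ls2), labelNodes(ls))
  expect_identical(setName(ls2), "anatomic")

  single <- labelSet(data.frame(id = 1L, abbrev = "Br", name = "Brain",
                                r = 255L, g = 0L, b = 0L,
                                parent = NA_integer_), "mini")
  f2 <- withr::local_tempfile(fileext = ".ilf")
  writeIlf(single, f2)
  p <- parseIlf(f2)
  expect_identical(nLabels(p), 1L)
  expect_identical(labelInfo(p, 1)$name, "Brain")

  set.seed(42)
  for (s in 1:5) {
    rs <- labelSet(randomNodeTable(9, seed = s), sprintf("rand%d", s))
    f3 <- withr::local_tempfile(fileext = ".ilf")
    writeIlf(rs, f3)
    expect_identical(labelNodes(parseIlf(f3)), labelNodes(rs))
  }
})

test_that("malformed ILF files are rejected with informative errors", {
  dup <- withr::local_tempfile(fileext = ".ilf")
  writeLines(c('<labelset name="x">',
               '<label id="5" abbrev="a" name="a" color="1,2,3"/>',
               '<label id="5" abbrev="b" name="b" color="4,5,6"/>',
               "</labelset>"), dup)
  expect_error(parseIlf(dup), "5", class = "atk_validation")

  badcol <- withr::local_tempfile(fileext = ".ilf")
  writeLines(c('<labelset name="x">',
               '<label id="1" abbrev="a" name="a" color="256,0"/>',
               "</labelset>"), badcol)
  err <- tryCatch(parseIlf(badcol), error = function(e) conditionMessage(e))
  expect_match(err, "color")
  expect_match(err, "line 2")
  expect_error(parseIlf(tempfile()), class = "atk_not_found")
})

test_that("labelSet validity enforces unique ids, resolvable parents and acyclicity", {
  tab <- randomNodeTable(5, seed = 1)
  tab$parent[3] <- 99L
  expect_error(labelSet(tab), "missing parent")
  tab2 <- randomNodeTable(4, seed = 2)
  tab2$id[2] <- tab2$id[1]
  expect_error(labelSet(tab2), "duplicate")
})

test_that("OBO parsing reduces is_a DAGs to trees deterministically", {
  chain <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "",
               "[Term]", "id: X:A", "name: term a", "is_a: X:B", "",
               "[Term]", "id: X:B", "name: term b", "is_a: X:C", "",
               "[Term]", "id: X:C", "name: term c"), chain)
  ls <- parseObo(chain)
  expect_identical(nLabels(ls), 3L)
  depths <- labelDepths(ls)
  rootId <- labelNodes(ls)$id[is.na(labelNodes(ls)$parent)]
  expect_identical(labelNodes(ls)$abbrev[match(rootId, labelNodes(ls)$id)], "X:C")
  expect_identical(max(depths), 2L)

  multi <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:P1", "name: p1", "",
               "[Term]", "id: X:P2", "name: p2", "",
               "[Term]", "id: X:K", "name: kid", "is_a: X:P2", "is_a: X:P1"),
             multi)
  lsm <- parseObo(multi)
  kid <- labelNodes(lsm)[labelNodes(lsm)$abbrev == "X:K", ]
  p1 <- labelNodes(lsm)[labelNodes(lsm)$abbrev == "X:P1", ]
  expect_identical(kid$parent, p1$id)      # lexically first parent kept
  expect_match(lsm@notes[1], "X:P2")       # dropped edge recorded

  cyc <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: X:A", "is_a: X:B", "",
               "[Term]", "id: X:B", "is_a: X:A"), cyc)
  expect_error(parseObo(cyc), "X:A", class = "atk_validation")
})

test_that("random OBO DAGs keep every node and form a forest", {
  set.seed(3)
  n <- 20L
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    lines <- c(lines, "[Term]", sprintf("id: T:%03d", i),
               sprintf("name: term %d", i))
    if (i > 1) {
      for (p in sample(seq_len(i - 1), min(i - 1, sample(0:2, 1)))) {
        lines <- c(lines, sprintf("is_a: T:%03d", p))
      }
    }
    lines <- c(lines, "")
  }
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(lines, f)
  ls <- parseObo(f)
  nd <- labelNodes(ls)
  expect_identical(nrow(nd), n)
  roots <- sum(is.na(nd$parent))
  expect_identical(sum(!is.na(nd$parent)), n - roots)  # edges = nodes - roots
})

test_that("descendants is inclusive and matches the recursive DFS oracle", {
  ls <- brainSet()
  expect_identical(descendants(ls, 9), 9L)                 # leaf
  expect_identical(descendants(ls, 2), c(2L, 4L, 5L, 9L))
  expect_identical(descendants(ls, 1), sort(labelIds(ls))) # root covers all
  expect_error(descendants(ls, 77), class = "atk_key")

  # complete binary tree of depth 3: 15 ids
  ids <- 1:15
  cbt <- labelSet(data.frame(
    id = ids, abbrev = paste0("n", ids), name = paste0("node ", ids),
    r = 0L, g = 0L, b = 0L,
    parent = c(NA_integer_, rep(ids, each = 2)[seq_len(14)])))
  expect_identical(descendants(cbt, 1), ids)
  for (s in 1:6) {
    tab <- randomNodeTable(12, seed = 100 + s)
    rs <- labelSet(tab)
    for (id in labelIds(rs)) {
      expect_identical(descendants(rs, id), oracleDescendants(tab, id))
    }
  }

  # path graph 1 -> 2 -> 3 -> 4 queried mid-chain
  path <- labelSet(data.frame(id = 1:4, abbrev = letters[1:4],
                              name = letters[1:4], r = 0L, g = 0L, b = 0L,
                              parent = c(NA, 1L, 2L, 3L)))
  expect_identical(descendants(path, 2), c(2L, 3L, 4L))
})

test_that("label text search is case-insensitive substring on abbrev or name", {
  ls <- brainSet()
  expect_true(9L %in% searchLabels(ls, "hypo"))
  expect_true(9L %in% searchLabels(ls, "DMH"))
  expect_true(9L %in% searchLabels(ls, "dmh"))
  expect_length(searchLabels(ls, "zzz"), 0L)
  expect_error(searchLabels(ls, ""), class = "atk_validation")
})

test_that("radial layout puts generation g on the circle of radius g * spacing", {
  single <- labelSet(data.frame(id = 1L, abbrev = "a", name = "a", r = 0L,
                                g = 0L, b = 0L, parent = NA_integer_))
  l1 <- layoutRadial(single, 2)
  expect_identical(c(l1$x, l1$y), c(0, 0))

  fan <- labelSet(data.frame(id = 1:5, abbrev = letters[1:5],
                             name = letters[1:5], r = 0L, g = 0L, b = 0L,
                             parent = c(NA, 1L, 1L, 1L, 1L)))
  lf <- layoutRadial(fan, 1)
  kids <- lf[lf$depth == 1, ]
  expect_equal(sqrt(kids$x^2 + kids$y^2), rep(1, 4), tolerance = 1e-9)
  ang <- sort(atan2(kids$y, kids$x) %% (2 * pi))
  expect_true(all(diff(ang) >= 2 * pi / 4 - 1e-9))

  for (s in 1:10) {
    rs <- labelSet(randomNodeTable(14, seed = 200 + s))
    sp <- 0.5 + s / 10
    lay <- layoutRadial(rs, sp)
    expect_equal(sqrt(lay$x^2 + lay$y^2), lay$depth * sp, tolerance = 1e-9)
    expect_identical(sort(lay$id), sort(labelIds(rs)))
  }
})

test_that("children occupy disjoint sectors nested within the parent's sector", {
  rs <- labelSet(randomNodeTable(14, seed = 33))
  lay <- layoutRadial(rs, 1)
  sect <- attr(lay, "sector")
  nd <- labelNodes(rs)
  for (i in seq_len(nrow(nd))) {
    p <- nd$parent[i]
    if (is.na(p)) next
    pi_ <- match(p, lay$id)
    ci <- match(nd$id[i], lay$id)
    expect_gte(sect[ci, 1], sect[pi_, 1] - 1e-12)
    expect_lte(sect[ci, 2], sect[pi_, 2] + 1e-12)
    sibs <- which(!is.na(nd$parent) & nd$parent == p)
    for (s2 in sibs) {
      if (nd$id[s2] == nd$id[i]) next
      si <- match(nd$id[s2], lay$id)
      lo <- max(sect[ci, 1], sect[si, 1]); hi <- min(sect[ci, 2], sect[si, 2])
      expect_lte(hi - lo, 1e-12)           # disjoint sectors
    }
  }
})

test_that("linear layout: x = depth * spacing, leaves consecutive, parents at child mean", {
  path <- labelSet(data.frame(id = 1:3, abbrev = letters[1:3],
                              name = letters[1:3], r = 0L, g = 0L, b = 0L,
                              parent = c(NA, 1L, 2L)))
  lp <- layoutLinear(path, 2)
  expect_identical(lp$x, c(0, 2, 4))

  bt <- labelSet(data.frame(id = 1:3, abbrev = letters[1:3],
                            name = letters[1:3], r = 0L, g = 0L, b = 0L,
                            parent = c(NA, 1L, 1L)))
  lb <- layoutLinear(bt, 1)
  expect_identical(lb$y[lb$id == 1], mean(lb$y[lb$id != 1]))

  for (s in 1:10) {
    rs <- labelSet(randomNodeTable(13, seed = 300 + s))
    lay <- layoutLinear(rs, 1.5)
    expect_equal(lay$x, lay$depth * 1.5)
    nd <- labelNodes(rs)
    isLeaf <- !nd$id %in% nd$parent[!is.na(nd$parent)]
    leafY <- lay$y[match(nd$id[isLeaf], lay$id)]
    expect_identical(sort(leafY), as.numeric(seq_len(sum(isLeaf)) - 1))
    for (i in which(!isLeaf)) {
      kids <- nd$id[!is.na(nd$parent) & nd$parent == nd$id[i]]
      expect_equal(lay$y[match(nd$id[i], lay$id)],
                   mean(lay$y[match(kids, lay$id)]))
    }
  }
})
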