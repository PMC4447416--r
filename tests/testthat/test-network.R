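test_that("networks store species and influences in canonical order", {
  net <- cmap_network(
    list(cmap_species("Z"), cmap_species("A", c_init = 1, clamped = TRUE)),
    list(cmap_influence("Z", "Z", 0.2, -1),
         cmap_influence("Z", "A", 0.5, +1)))
  expect_equal(species_names(net), c("A", "Z"))
  expect_equal(vapply(net$influences, function(i) i$sources, ""),
               c("A", "Z"))
  expect_equal(initial_state(net), c(A = 1, Z = 0))
})

test_that("validator reports bound violations, dangling names, duplicates", {
  ok <- load_network(fixture("insulin_cmap.json"))
  expect_length(validate_network(ok), 0)

  bad <- ok
  bad$species[[1]]$c_init <- 1.2
  v <- validate_network(bad)
  expect_length(v, 1)
  expect_match(v, "c_init")

  bad <- ok
  bad$influences[[1]]$weight <- 1.5
  expect_match(validate_network(bad), "weight")

  dangling <- cmap_network(list(cmap_species("A")), check = FALSE)
  dangling$influences <- list(cmap_influence("A", "ghost", 0.5, 1))
  v <- validate_network(dangling)
  expect_length(v, 1)
  expect_match(v, "ghost")

  expect_error(
    cmap_network(list(cmap_species("A")),
                 list(cmap_influence("A", "A", 0.5, 1),
                      cmap_influence("A", "A", 0.4, 1))),
    "duplicated influence")
  # identical triples are allowed when they stand for different rate
  # constants (distinct provenance labels)
  expect_silent(
    cmap_network(list(cmap_species("A")),
                 list(cmap_influence("A", "A", 0.5, 1, label = "k1"),
                      cmap_influence("A", "A", 0.5, 1, label = "k2"))))
  expect_match(validate_network(list(species = list())), "at least one")
})

test_that("clamped species may exceed their own c_max up to 1", {
  s <- cmap_species("in", c_init = 0.9, c_max = 0.5, clamped = TRUE)
  expect_length(validate_network(cmap_network(list(s), check = FALSE)), 0)
  s2 <- cmap_species("x", c_init = 0.9, c_max = 0.5)
  expect_match(validate_network(cmap_network(list(s2), check = FALSE)),
               "c_init")
})

test_that("load/save round-trips the packaged fixtures byte-identically", {
  for (f in c("insulin_cmap.json")) {
    path <- fixture(f)
    tmp <- withr::local_tempfile(fileext = ".json")
    save_network(load_network(path), tmp)
    expect_identical(readLines(tmp), readLines(path))
  }
})

test_that("a minimal one-species file loads as a network of size 1", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"species": [{"name": "A"}], "influences": []}', tmp)
  net <- load_network(tmp)
  expect_length(net$species, 1)
  expect_length(net$influences, 0)
})

test_that("the insulin fixture has 27 dynamic species plus 2 clamped inputs", {
  net <- load_network(fixture("insulin_cmap.json"))
  clamped <- vapply(net$species, `[[`, FALSE, "clamped")
  expect_length(net$species, 29)
  expect_equal(sum(clamped), 2)
  expect_setequal(species_names(net)[clamped], c("insulin", "diabetes"))
})

test_that("schema violations are errors naming the offending field", {
  tmp <- withr::local_tempfile(fileext = ".json")
  writeLines('{"species": [{"name": "A"}]}', tmp)
  expect_error(load_network(tmp), "influences")
  writeLines('{"species": [{"c_init": 0}], "influences": []}', tmp)
  expect_error(load_network(tmp), "name")
  writeLines(paste0('{"species": [{"name": "A"}], "influences": ',
                    '[{"target": "A", "sources": ["A"], "sign": 1}]}'), tmp)
  expect_error(load_network(tmp), "weight")
  # out-of-range weight is caught by validation
  writeLines(paste0('{"species": [{"name": "A"}], "influences": ',
                    '[{"target": "A", "sources": ["A"], "weight": 1.5, ',
                    '"sign": 1}]}'), tmp)
  expect_error(load_network(tmp), "weight 1.5")
  expect_error(load_network(withr::local_tempfile()), "no such file")
})

test_that("set_initial replaces values without touching the input", {
  net <- build_motif("positive")
  net2 <- set_initial(net, c(P = 0.4))
  expect_equal(initial_state(net2)[["P"]], 0.4)
  expect_equal(initial_state(net)[["P"]], 0)
  expect_error(set_initial(net, c(Q = 0.4)), "unknown species")
  expect_error(set_initial(net, c(P = 1.4)), "invalid")
})

test_that("conditions round-trip through their file format", {
  cond <- cmap_condition("t2d", scale = c(IR = 0.55, GLUT4 = 0.5,
                                          diabetes = 0.15))
  tmp <- withr::local_tempfile(fileext = ".json")
  save_condition(cond, tmp)
  back <- load_condition(tmp)
  expect_equal(back$scale, cond$scale)
  expect_equal(back$name, "t2d")
  expect_error(cmap_condition("x", scale = c(IR = -1)), "factors")
})
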