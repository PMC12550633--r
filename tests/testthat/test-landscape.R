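test_that("canonical landscape carries the published potentials and distances", {
  ls <- canonical_landscape()
  expect_equal(nrow(ls$cofactors), 8)
  expect_equal(nrow(ls$edges), 6)
  pot <- setNames(ls$cofactors$potential, ls$cofactors$id)
  expect_equal(pot[["WH1"]], 1.9)
  expect_equal(pot[["WH2"]], 1.75)
  expect_equal(pot[["Thot"]], 1.6)
  expect_equal(pot[["WL1"]], 1.1)
  expect_equal(pot[["WL2"]], 1.05)
  expect_equal(pot[["Tcold"]], 1.0)
  expect_equal(pot[["W1"]], 1.1)
  expect_equal(pot[["W2"]], 1.1)
  # only the dimer-to-cold-relay edge is long
  d <- ls$edges$distance
  long <- ls$edges$from == "W2" & ls$edges$to == "WL1"
  expect_equal(d[long], 10)
  expect_true(all(d[!long] == 5))
  expect_equal(ls$interactions$epsilon, 1.6)
  expect_equal(ls$temperature, 300)
})

test_that("dimer repulsion yields the 2.7 V effective first-hole potential", {
  ls <- canonical_landscape()
  occ <- setNames(c(1, 1, rep(0, 6)), ls$cofactors$id)
  expect_equal(effective_potential(ls, "W1", occ), 2.7)
  expect_equal(effective_potential(ls, "W2", occ), 2.7)
  # after the first hole departs, the survivor relaxes to its intrinsic value
  occ["W1"] <- 0
  expect_equal(effective_potential(ls, "W2", occ), 1.1)
})

test_that("validation names the offending field", {
  ls <- canonical_landscape()
  bad <- ls; bad$edges$to[1] <- "WX"
  expect_error(validate_landscape(bad), "WX")
  bad <- ls; bad$edges$distance[2] <- -1
  expect_error(validate_landscape(bad), "distance")
  bad <- ls; bad$cofactors$id[2] <- "W1"
  expect_error(validate_landscape(bad), "duplicate")
  bad <- ls; bad$edges <- ls$edges[-1, ]
  expect_error(validate_landscape(bad), "disconnected")
  bad <- ls; bad$interactions$epsilon <- -0.5
  expect_error(validate_landscape(bad), "epsilon")
  expect_error(landscape(ls$cofactors, rbind(ls$edges, ls$edges[1, ]),
                         ls$interactions),
               "duplicate edge")
})

test_that("YAML config round-trips to an identical landscape", {
  ls <- canonical_landscape()
  path <- withr::local_tempfile(fileext = ".yaml")
  save_landscape(ls, path)
  re <- load_landscape(path)
  expect_equal(re$cofactors, ls$cofactors)
  expect_equal(re$edges, ls$edges)
  expect_equal(re$interactions, ls$interactions)
  expect_equal(re$temperature, ls$temperature)
  expect_equal(unclass(re$rate_params), unclass(ls$rate_params))
})

test_that("loader reports missing fields and unknown references by name", {
  path <- withr::local_tempfile(fileext = ".yaml")
  ls <- canonical_landscape()
  save_landscape(ls, path)
  doc <- yaml::read_yaml(path)
  doc$edges[[1]]$to <- "WX"
  yaml::write_yaml(doc, path)
  expect_error(load_landscape(path), "WX")
  doc$edges[[1]]$to <- "WH1"
  doc$temperature_K <- NULL
  yaml::write_yaml(doc, path)
  expect_error(load_landscape(path), "temperature_K")
  doc2 <- yaml::read_yaml(path)
  doc2$temperature_K <- 300
  doc2$cofactors[[1]]$potential_V <- NULL
  yaml::write_yaml(doc2, path)
  expect_error(load_landscape(path), "potential_V")
})

test_that("packaged YAML fixture equals the in-code constructor", {
  path <- system.file("extdata", "canonical_landscape.yaml", package = "hbnet")
  re <- load_landscape(path)
  ls <- canonical_landscape()
  expect_equal(re$cofactors, ls$cofactors)
  expect_equal(re$edges, ls$edges)
  expect_equal(unclass(re$rate_params), unclass(ls$rate_params))
})
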