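test_that("the default config encodes the reconciliation rules", {
  m <- pkg_map()
  barley <- m[["boiled_barley_rice"]]
  src <- vapply(barley$components, `[[`, character(1), "source")
  w <- vapply(barley$components, `[[`, numeric(1), "weight")
  expect_setequal(src, c("RICE_INDIVIDUAL", "Wheat flour"))
  expect_equal(w[src == "RICE_INDIVIDUAL"], 0.7)
  expect_equal(w[src == "Wheat flour"], 0.3)

  liver <- m[["liver"]]
  expect_length(liver$components, 1)
  expect_equal(liver$components[[1]]$weight, 1.0)
  expect_setequal(liver$components[[1]]$average_of,
                  c("Beef liver", "Pork liver", "Chicken liver",
                    "Hinai chicken liver", "Innards of Hinai chicken"))
})

test_that("invalid configs are rejected", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("bad_item:", "  components:",
               "    - {source: itemX, weight: 0.5}",
               "    - {source: itemX, weight: 0.6}"), tmp)
  expect_error(read_mapping(tmp), "sum")
  writeLines(c("dangling:", "  components:",
               "    - {source: no_such_item, weight: 1.0}"), tmp)
  expect_error(read_mapping(tmp, table = tiny_conc_table()), "absent")
})

test_that("resolution produces the documented effective concentrations", {
  tab <- pkg_conc()
  m <- pkg_map()
  # tofu: average of silken (0.015) and cotton (0.027) tofu
  expect_equal(resolve_concentration(m[["tofu"]], tab), 0.021,
               tolerance = 1e-3)
  # mushrooms: half shiitake (0.374), half maitake (0.043)
  expect_equal(resolve_concentration(m[["mushrooms"]], tab), 0.2085,
               tolerance = 1e-3)
  # exclusions resolve to zero
  expect_identical(resolve_concentration(m[["fruit"]], tab), 0)
  expect_identical(resolve_concentration(m[["milk"]], tab), 0)
})

test_that("individual rice resolution uses the subject, fallback and brown-rice factor", {
  m <- pkg_map()
  tab <- pkg_conc()
  s <- tiny_subjects(rice_cd = 0.2)
  expect_equal(resolve_concentration(m[["rice"]], tab, subject = s), 0.2)
  s$brown_rice <- TRUE
  expect_equal(resolve_concentration(m[["rice"]], tab, subject = s), 0.18)
  s$rice_cd_mg_per_kg <- NA
  expect_error(resolve_concentration(m[["rice"]], tab, subject = s),
               "geometric mean")
  expect_equal(resolve_concentration(m[["rice"]], tab, subject = s,
                                     cohort_rice_gm = 0.1),
               0.9 * 0.1)
})

test_that("resolution is linear in the concentration table", {
  tab <- pkg_conc()
  m <- pkg_map()
  scaled <- tab
  scaled$value <- scaled$value * 3
  for (key in c("tofu", "mushrooms", "udon_and_soba", "liver")) {
    expect_equal(resolve_concentration(m[[key]], scaled),
                 3 * resolve_concentration(m[[key]], tab))
  }
  # weight-1 averages stay inside the span of their sources
  for (key in c("tofu", "liver", "other_shellfish")) {
    refs <- m[[key]]$components[[1]]$average_of
    ams <- vapply(refs, function(it) pooled_mean(tab, it), numeric(1))
    r <- resolve_concentration(m[[key]], tab)
    expect_gte(r, min(ams)); expect_lte(r, max(ams))
  }
})

test_that("coverage audit reproduces the exclusion lists", {
  rep <- validate_coverage(pkg_map(), table = pkg_conc())
  expect_true(all(c("Garlic", "Okra", "Belvedere fruit", "Kelp",
                    "Hijiki seaweed", "Agar-agar", "Mozuku seaweed",
                    "Scallops with innards") %in%
                  rep$unused_concentration_items))
  expect_true(all(c("animal_meat", "eggs", "milk", "brewed_green_tea") %in%
                  rep$excluded_items))
  expect_length(rep$unmapped_dhq_items, 0)
  # vacuous mapping: everything unmapped
  empty <- structure(list(), class = "dhq_mapping")
  rep0 <- validate_coverage(empty, catalog = c("a", "b"),
                            table = tiny_conc_table())
  expect_setequal(rep0$unmapped_dhq_items, c("a", "b"))
})
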