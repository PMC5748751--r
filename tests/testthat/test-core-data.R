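test_that("packaged study loads fully cross-linked", {
  expect_s3_class(fang, "flav_study")
  expect_equal(nrow(fang$compounds), 30)
  expect_equal(nrow(fang$transport), 30)
  expect_equal(nrow(fang$accumulation), 30)
  expect_equal(nrow(fang$descriptors), 28)
  expect_equal(sum(fang$descriptors$split == "training"), 22)
  expect_equal(sum(fang$descriptors$split == "test"), 6)
  expect_true(all(fang$descriptors$compound_id %in% fang$compounds$compound_id))
  # glycoside flag is derivable from the substituent map (validated on load)
  expect_equal(fang$compounds$compound_id[fang$compounds$is_glycoside],
               c(8L, 16L, 17L, 20L, 24L, 30L))
})

test_that("missing measurements stay coded, never zero, and nothing is NaN", {
  ac <- fang$accumulation
  nd_nt <- !is.na(ac$ca_ab_code)
  expect_true(all(is.na(ac$ca_ab[nd_nt])))
  expect_setequal(ac$compound_id[ac$ca_ab_code %in% "NT"], 10L)
  expect_setequal(ac$compound_id[ac$ca_ab_code %in% "ND"],
                  c(14L, 16L, 17L, 22L, 24L))
  # ND (not detected) and NT (not tested) are distinct codes
  expect_false(any(ac$ca_ab == 0, na.rm = TRUE))
  for (tbl in unclass(fang)) {
    num <- vapply(tbl, is.numeric, logical(1))
    expect_false(any(vapply(tbl[num], function(col) any(is.nan(col)),
                            logical(1))))
  }
  st <- fang$stability
  expect_equal(st$rel_conc_code[st$compound_id == 14], "ND")
  expect_true(is.na(st$rel_conc[st$compound_id == 14]))
})

test_that("Papp converts to pPapp and back", {
  expect_equal(papp_to_ppapp(22.35e-6), 4.651, tolerance = 1e-4)
  expect_equal(papp_to_ppapp(33.90e-6), 4.470, tolerance = 1e-4)
  expect_identical(papp_to_ppapp(1e-5), 5)
  papp <- fang$transport$papp_ab
  expect_equal(ppapp_to_papp(papp_to_ppapp(papp)), papp, tolerance = 1e-12)
  expect_error(papp_to_ppapp(0), class = "flavperm_domain_error")
  expect_error(papp_to_ppapp(-1e-6), class = "flavperm_domain_error")
})

test_that("experimental pPapp agrees with the transport table at printed precision", {
  joined <- dplyr::inner_join(fang_test, fang$transport, by = "compound_id")
  conv <- papp_to_ppapp(joined$papp_ab)
  # five test compounds have 3-4 significant printed digits: 0.001 agreement
  well_resolved <- joined$compound_id != 14
  expect_true(all(abs(conv[well_resolved] -
                        joined$ppapp_exp[well_resolved]) < 0.001))
  # compound 14's Papp is printed to two significant figures (0.29e-6);
  # check consistency at that precision instead
  pp14 <- joined$ppapp_exp[joined$compound_id == 14]
  expect_equal(round(ppapp_to_papp(pp14) * 1e6, 2),
               joined$papp_ab[joined$compound_id == 14] * 1e6)
})

test_that("write_study/load_study and JSON serialization round trip", {
  dir <- withr::local_tempdir()
  write_study(fang, dir)
  back <- load_study(dir)
  expect_equal(back, fang, tolerance = 1e-12)

  json <- withr::local_tempfile(fileext = ".json")
  study_to_json(fang, json)
  back2 <- study_from_json(json)
  expect_equal(back2, fang, tolerance = 1e-12)
})

test_that("loader rejects malformed inputs", {
  expect_error(load_study("no-such-fixture"), "missing file",
               class = "flavperm_io_error")

  dir <- withr::local_tempdir()
  write_study(fang, dir)

  # empty file -> malformed header
  writeLines(character(), file.path(dir, "transport.csv"))
  expect_error(load_study(dir), "malformed header",
               class = "flavperm_schema_error")

  # duplicate compound_id
  write_study(fang, dir)
  tr <- readr::read_csv(file.path(dir, "transport.csv"),
                        show_col_types = FALSE)
  readr::write_csv(rbind(tr, tr[1, ]), file.path(dir, "transport.csv"))
  expect_error(load_study(dir), "duplicate compound_id",
               class = "flavperm_schema_error")

  # non-numeric cell outside the missing codes
  write_study(fang, dir)
  tr$papp_ab_mean[3] <- "oops"
  readr::write_csv(tr, file.path(dir, "transport.csv"))
  expect_error(load_study(dir), "non-numeric cell",
               class = "flavperm_parse_error")

  # unknown compound_id in a linked table
  write_study(fang, dir)
  ac <- readr::read_csv(file.path(dir, "accumulation.csv"),
                        show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  ac$id[1] <- "99"
  readr::write_csv(ac, file.path(dir, "accumulation.csv"))
  expect_error(load_study(dir), "unknown compound_id",
               class = "flavperm_schema_error")

  # glycoside flag inconsistent with substituent map
  write_study(fang, dir)
  co <- readr::read_csv(file.path(dir, "compounds.csv"),
                        show_col_types = FALSE)
  co$is_glycoside[co$id == 8] <- FALSE
  readr::write_csv(co, file.path(dir, "compounds.csv"))
  expect_error(load_study(dir), "is_glycoside",
               class = "flavperm_schema_error")
})
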