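# Threshold-based phenotype calls: the published fixed thresholds, the
# documented strict-inequality tie rule, and monotonicity in intensity.

mk_cells <- function(...) {
  vals <- list(...)
  base <- data.frame(cell_id = sprintf("c%d", seq_len(length(vals[[1]]))))
  for (col in c("nucleus_FITC", "cytoplasm_FITC", "membrane_FITC",
                "nucleus_Cy5", "cytoplasm_Cy5", "membrane_Cy5")) {
    base[[col]] <- if (col %in% names(vals)) vals[[col]] else 0
  }
  base
}

test_that("lymphocyte classification follows the fixed slide thresholds", {
  # nuclear FITC 0.20 > 0.15 with Cy5 dark: CD3+CD8-
  # all dark: negative; nuclear 0.16/0.14 exceed both: CD3+CD8+
  cells <- mk_cells(nucleus_FITC = c(0.20, 0, 0.16),
                    nucleus_Cy5 = c(0, 0, 0.14))
  expect_equal(classify_lymphocyte(cells),
               c("CD3only", "negative", "CD3CD8"))
  # exactly at a threshold is negative (strict inequality)
  cells <- mk_cells(nucleus_FITC = 0.15, nucleus_Cy5 = 0.132)
  expect_equal(classify_lymphocyte(cells), "negative")
  # missing compartment intensity names the cell
  cells <- mk_cells(nucleus_FITC = c(0.2, NA))
  expect_error(classify_lymphocyte(cells), "c2")
})

test_that("macrophage classification uses the macrophage-slide FITC threshold", {
  cells <- mk_cells(nucleus_FITC = c(0.25, 0.25, 0.15),
                    nucleus_Cy5 = c(0, 0.20, 0))
  # 0.15 is above the lymphocyte FITC threshold but below the macrophage
  # slide threshold of 0.200, so the third cell is negative
  expect_equal(classify_macrophage(cells),
               c("CD68only", "CD68CD163", "negative"))
})

test_that("positivity rules combine compartments as configured", {
  cells <- mk_cells(cytoplasm_FITC = 0.6, membrane_FITC = 0.6)
  expect_equal(classify_lymphocyte(cells, rule = "any"), "CD3only")
  expect_equal(classify_lymphocyte(cells, rule = "nucleus"), "negative")
  expect_equal(classify_lymphocyte(cells, rule = "cyto_and_membrane"), "CD3only")
  cells <- mk_cells(cytoplasm_FITC = 0.6)  # membrane dark
  expect_equal(classify_lymphocyte(cells, rule = "cyto_and_membrane"), "negative")
})

test_that("classification is monotone and partitions every cell", {
  set.seed(3)
  for (rep in 1:20) {
    cells <- mk_cells(nucleus_FITC = runif(10, 0, 0.3),
                      cytoplasm_FITC = runif(10, 0, 0.6),
                      membrane_FITC = runif(10, 0, 0.6),
                      nucleus_Cy5 = runif(10, 0, 0.3),
                      cytoplasm_Cy5 = runif(10, 0, 0.1),
                      membrane_Cy5 = runif(10, 0, 0.1))
    ph <- classify_lymphocyte(cells)
    expect_true(all(ph %in% c("CD3only", "CD8only", "CD3CD8", "negative")))
    # raising any intensity never removes a positive call
    raised <- cells
    raised$nucleus_FITC <- raised$nucleus_FITC + 0.2
    ph2 <- classify_lymphocyte(raised)
    cd3_before <- ph %in% c("CD3only", "CD3CD8")
    cd3_after <- ph2 %in% c("CD3only", "CD3CD8")
    expect_true(all(cd3_after >= cd3_before))
    cd8_before <- ph %in% c("CD8only", "CD3CD8")
    cd8_after <- ph2 %in% c("CD8only", "CD3CD8")
    expect_true(all(cd8_after == cd8_before))
  }
})

test_that("PCK dichotomization applies the 2.16e-2 threshold strictly", {
  expect_equal(dichotomize_pck(0.03), "high")
  expect_equal(dichotomize_pck(0.0), "low")
  expect_equal(dichotomize_pck(2.16e-2), "low")  # boundary -> low
  expect_error(dichotomize_pck(-0.1), "negative")
})

test_that("tumor mask passthrough and disc-union buffering", {
  sq <- square_case()
  mask <- tumor_mask_from_pck(polygon = sq$tumor)
  expect_identical(mask$polygon, sq$tumor)
  expect_equal(mask$area_um2(), 2000^2)

  # one PCK+ cell, 20-um buffer: disc of area pi * 20^2 within 1%
  mask <- tumor_mask_from_pck(pck_centroids = rbind(c(100, 100)),
                              buffer_um = 20)
  expect_true(mask$contains(110, 100))
  expect_false(mask$contains(121, 100))
  expect_equal(mask$area_um2(), pi * 400, tolerance = 0.01)

  # no PCK+ cells -> empty mask, area 0
  mask <- tumor_mask_from_pck(pck_centroids = matrix(numeric(0), ncol = 2))
  expect_equal(mask$area_um2(), 0)
  expect_false(any(mask$contains(c(1, 2), c(1, 2))))

  expect_error(tumor_mask_from_pck(), "supply")
})
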