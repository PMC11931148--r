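test_that("region volumes are count x voxel volume and sum to foreground", {
  sch <- label_scheme(data.frame(id = 1:2, name = c("a", "b"),
                                 tissue = c("GM", "WM"),
                                 hemisphere = c("NA", "NA")))
  lab <- array(0L, dim = c(10, 10, 10)); lab[1:10, 1:10, 1] <- 1L
  lm <- labelmap3d(lab, diag(4), sch)
  rv <- region_volumes(lm)
  expect_equal(unname(rv["a"]), 100 * 0.001)
  expect_equal(unname(rv["b"]), 0)
  ph <- small_phantom()
  rv2 <- region_volumes(ph$labels)
  expect_equal(sum(rv2), sum(ph$labels$labels != 0) * voxel_volume_ml(ph$labels),
               tolerance = 1e-12)
  # phantom thalamus counted volume vs analytic ellipsoid (coarse 4 mm grid)
  expect_lt(abs(rv2[["thalamus_left"]] - ph$analytic_volumes[["thalamus_left"]]) /
              ph$analytic_volumes[["thalamus_left"]], 0.25)
})

test_that("lesion-free volumes satisfy total - lesion per region", {
  ph <- small_phantom()
  rep_ <- lesion_free_volumes(ph$labels, ph$lesion_masks)
  expect_true(all(abs(rep_$lesion_free_ml -
                        (rep_$total_ml - rep_$lesion_ml)) <= 1e-9))
  expect_true(all(rep_$lesion_ml <= rep_$total_ml + 1e-12))
  expect_true(all(rep_$total_ml >= 0))
  # empty mask: lesion-free equals total everywhere
  rep0 <- lesion_free_volumes(ph$labels, NULL)
  expect_identical(rep0$lesion_free_ml, rep0$total_ml)
  # lesion fully inside one region with known volume
  vv <- voxel_volume_ml(ph$labels)
  wm_row <- which(rep_$region == "cerebral_wm")
  un <- Reduce(`|`, ph$lesion_masks)
  expect_equal(rep_$lesion_ml[wm_row], sum(un) * vv)   # lesions are WM-only
  others <- rep_$region != "cerebral_wm"
  expect_identical(rep_$lesion_free_ml[others], rep_$total_ml[others])
  # brute-force voxel intersection oracle per region
  for (rg in c("cerebral_wm", "thalamus_left")) {
    id <- ph$scheme$entries$id[ph$scheme$entries$name == rg]
    expect_equal(rep_$lesion_ml[rep_$region == rg],
                 sum(un & ph$labels$labels == id) * vv)
  }
  # lesion voxels on background warn
  bgmask <- array(FALSE, dim = dim(un)); bgmask[1, 1, 1] <- TRUE
  expect_warning(lesion_free_volumes(ph$labels, bgmask), "background")
})

test_that("hemisphere splitting follows world x and conserves volume", {
  ph <- small_phantom(seed = 8, lesions = FALSE)
  split <- split_hemispheres(ph$labels)
  rv_split <- region_volumes(split)
  rv <- region_volumes(ph$labels)
  # splitting then summing equals the unsplit volumes
  for (rg in c("csf", "cortical_gm", "cerebral_wm")) {
    parts <- rv_split[paste0(rg, c("_left", "_right", "_midline"))]
    expect_equal(sum(parts), rv[[rg]], tolerance = 1e-9)
  }
  # pre-tagged structures keep their ids
  expect_equal(sum(split$labels == 4L), sum(ph$labels$labels == 4L))
  # symmetric phantom: left/right within 1%
  for (rg in c("csf", "cortical_gm", "cerebral_wm")) {
    l <- rv_split[[paste0(rg, "_left")]]; r <- rv_split[[paste0(rg, "_right")]]
    expect_lt(abs(l - r) / mean(c(l, r)), 0.01)
  }
  # voxel at positive world x is RIGHT
  wx <- brainquant:::.world_axes(dim(ph$labels$labels), 4)$x
  i_pos <- which(wx > 3)[1]
  lab_val <- split$labels[i_pos, 16, 16]
  if (lab_val != 0) {
    hemi <- split$scheme$entries$hemisphere[split$scheme$entries$id == lab_val]
    expect_equal(hemi, "RIGHT")
  }
  # degenerate all-midline plane
  sch <- label_scheme(data.frame(id = 1L, name = "m", tissue = "GM",
                                 hemisphere = "NA"))
  aff <- diag(4)  # world x = voxel index - 0 ... single-voxel x plane at 0
  lab <- array(1L, dim = c(1, 4, 4))
  sp <- split_hemispheres(labelmap3d(lab, aff, sch))
  hemi_of <- sp$scheme$entries$hemisphere[match(unique(as.vector(sp$labels)),
                                                sp$scheme$entries$id)]
  expect_true(all(hemi_of == "MIDLINE"))
})

test_that("relative asymmetry matches the closed form and is antisymmetric", {
  rep_ <- data.frame(region = c("thal_left", "thal_right"),
                     hemisphere = c("LEFT", "RIGHT"),
                     total_ml = c(10, 5.12), lesion_ml = 0,
                     lesion_free_ml = c(10, 5.12))
  class(rep_) <- c("volume_report", "data.frame")
  # affected RIGHT, shrunk by 0.8^3: 100*(0.512-1)/0.756 = -64.5503
  a <- relative_asymmetry(rep_, hemisphere_assignment("LEFT"))
  expect_equal(a$asymmetry_pct, 100 * (5.12 - 10) / 7.56, tolerance = 1e-9)
  expect_lt(abs(a$asymmetry_pct - (-64.55)), 0.01)
  # equal volumes -> 0
  rep_eq <- rep_; rep_eq$lesion_free_ml <- c(7, 7); rep_eq$total_ml <- c(7, 7)
  expect_equal(relative_asymmetry(rep_eq,
                                  hemisphere_assignment("LEFT"))$asymmetry_pct, 0)
  # antisymmetric under swapping the affected side
  b <- relative_asymmetry(rep_, hemisphere_assignment("RIGHT"))
  expect_equal(a$asymmetry_pct, -b$asymmetry_pct)
  # both-zero regions are reported missing
  rep_z <- rep_; rep_z$lesion_free_ml <- c(0, 0)
  expect_true(is.na(relative_asymmetry(rep_z,
                                       hemisphere_assignment("LEFT"))$asymmetry_pct))
  # one hemisphere missing errors with the region name
  expect_error(relative_asymmetry(rep_[1, ], hemisphere_assignment("LEFT")),
               "thal")
})

test_that("affected hemisphere is contralateral to the clinical side", {
  expect_equal(hemisphere_assignment("LEFT")$affected_hemisphere, "RIGHT")
  expect_equal(hemisphere_assignment("RIGHT")$affected_hemisphere, "LEFT")
})

test_that("atlas postprocessing partitions WM/CGM and matches intersections", {
  ph <- small_phantom(seed = 10, lesions = FALSE)
  lab <- ph$labels$labels
  tis <- ph$scheme$entries$tissue[match(lab, ph$scheme$entries$id)]
  wm <- array(!is.na(tis) & tis == "WM", dim = dim(lab))
  gm <- array(!is.na(tis) & tis == "GM", dim = dim(lab))
  lobar <- atlas_postprocess(wm, gm, ph$atlas)
  e <- lobar$scheme$entries
  # WM conservation: lobar + PLIC + generic WM = total WM
  wm_ids <- e$id[e$tissue == "WM"]
  expect_equal(sum(lobar$labels %in% wm_ids), sum(wm))
  gm_ids <- e$id[e$tissue == "GM"]
  expect_equal(sum(lobar$labels %in% gm_ids), sum(gm))
  # a WM voxel in a lobar territory gets that lobe's WM id
  fl <- ph$atlas$labels == 1L & wm    # frontal_left territory
  expect_true(all(lobar$labels[fl] == e$id[e$name == "wm_frontal_left"]))
  # PLIC voxel counts equal brute-force mask-box intersections
  for (side in c("left", "right")) {
    tid <- ph$atlas$scheme$entries$id[ph$atlas$scheme$entries$name ==
                                        paste0("plic_", side)]
    oid <- e$id[e$name == paste0("plic_", side)]
    expect_equal(sum(lobar$labels == oid),
                 sum(wm & ph$atlas$labels == tid))
  }
  expect_error(atlas_postprocess(wm, wm, ph$atlas), "overlap")
})

test_that("volume report writes CSV and JSON", {
  tmp <- withr::local_tempdir()
  ph <- small_phantom()
  rep_ <- lesion_free_volumes(ph$labels, ph$lesion_masks)
  write_volume_report(rep_, file.path(tmp, "r.csv"))
  write_volume_report(rep_, file.path(tmp, "r.json"))
  rc <- utils::read.csv(file.path(tmp, "r.csv"))
  expect_equal(rc$lesion_free_ml, rep_$lesion_free_ml)
  rj <- jsonlite::read_json(file.path(tmp, "r.json"), simplifyVector = TRUE)
  expect_equal(rj$total_ml, rep_$total_ml)
})
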