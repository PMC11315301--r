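# Image IO: windowing, normalization, format round-trips, dataset assembly.

test_that("HU display windowing maps the window edges and midpoint correctly", {
  w <- pseudohealthy:::.apply_window
  expect_equal(w(40, c(40, 80)), 0.5)       # window center -> mid gray
  expect_equal(w(-1000, c(40, 80)), 0)      # far below -> clamped black
  expect_equal(w(0, c(40, 80)), 0)          # lower edge
  expect_equal(w(80, c(40, 80)), 1)         # upper edge
  hu <- sort(runif(100, -200, 300))
  expect_true(all(diff(w(hu, c(40, 80))) >= 0))  # monotone in HU
})

test_that("normalize_unit rescales affinely, handles constants, is idempotent", {
  img <- matrix(c(0, 128, 255, 64), 2, 2)
  out <- normalize_unit(img)
  expect_equal(sort(as.vector(out)), sort(c(0, 128 / 255, 1, 64 / 255)))
  expect_equal(unclass(normalize_unit(matrix(3.3, 4, 4))), matrix(0, 4, 4),
               ignore_attr = TRUE)
  set.seed(1)
  r <- matrix(runif(64, -5, 9), 8, 8)
  n1 <- normalize_unit(r)
  expect_equal(unclass(normalize_unit(n1)), unclass(n1), ignore_attr = TRUE)
})

test_that("PNG save/load round-trips at the writer's 8-bit quantization", {
  set.seed(2)
  img <- round(matrix(runif(256), 16, 16) * 255) / 255
  f <- tempfile(fileext = ".png")
  save_slice(img, f)
  back <- load_slice(f)
  expect_equal(unclass(back), img, ignore_attr = TRUE)
  expect_identical(attr(back, "scale"), "unit")
})

test_that("16-bit grayscale PNG written by an independent tool reads exactly", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  f <- tempfile(fileext = ".png")
  code <- sprintf("
import numpy as np
from PIL import Image
rng = np.random.default_rng(5)
a = rng.integers(0, 65536, size=(12, 12), dtype=np.uint16)
Image.fromarray(a, mode='I;16').save(%s)
np.savetxt(%s, a, fmt='%%d')
", shQuote(f), shQuote(paste0(f, ".txt")))
  res <- system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(f), "PIL unavailable")
  ref <- as.matrix(read.table(paste0(f, ".txt")))
  img <- load_slice(f)
  expect_equal(unclass(img), unname(ref) / 65535, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("NIfTI slices load with windowing applied to stored values", {
  hu <- matrix(seq(-50, 149, length.out = 64), 8, 8)
  f <- tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(hu), f)
  img <- load_slice(f, window = c(40, 80))
  expect_equal(unclass(img), pmin(pmax((hu - 0) / 80, 0), 1),
               ignore_attr = TRUE, tolerance = 1e-6)
  img2 <- load_slice(f)  # min-max without a window
  expect_equal(range(img2), c(0, 1))
})

test_that("minimal DICOM reader agrees with a pydicom-written fixture", {
  skip_if(Sys.which("python") == "", "python not on PATH")
  f <- tempfile(fileext = ".dcm")
  code <- sprintf("
import numpy as np, pydicom
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian
rng = np.random.default_rng(9)
arr = rng.integers(-100, 200, size=(10, 14)).astype(np.int16)
meta = FileMetaDataset()
meta.MediaStorageSOPClassUID = pydicom.uid.CTImageStorage
meta.MediaStorageSOPInstanceUID = pydicom.uid.generate_uid()
meta.TransferSyntaxUID = ExplicitVRLittleEndian
ds = Dataset()
ds.file_meta = meta
ds.Rows, ds.Columns = arr.shape
ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
ds.PixelRepresentation = 1
ds.SamplesPerPixel = 1
ds.PhotometricInterpretation = 'MONOCHROME2'
ds.RescaleSlope = '1'; ds.RescaleIntercept = '-1024'
ds.PixelData = arr.tobytes()
ds.save_as(%s, implicit_vr=False, little_endian=True, enforce_file_format=True)
np.savetxt(%s, arr, fmt='%%d')
", shQuote(f), shQuote(paste0(f, ".txt")))
  system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE)
  skip_if(!file.exists(f), "pydicom unavailable")
  ref <- unname(as.matrix(read.table(paste0(f, ".txt"))))
  dc <- read_dicom_slice(f)
  expect_equal(unname(dc$pixels), ref)
  expect_equal(dc$slope, 1)
  expect_equal(dc$intercept, -1024)
  # windowed load applies slope/intercept first, then the display window
  img <- load_slice(f, format = "dicom", window = c(40, 80))
  hu <- ref - 1024
  expect_equal(unclass(img), pmin(pmax((hu - 0) / 80, 0), 1),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("dataset assembly enforces split and mask invariants", {
  set.seed(3)
  imgs <- replicate(10, matrix(runif(16), 4, 4), simplify = FALSE)
  pats <- rep(c("a", "b"), each = 5)
  ds <- assemble_dataset(imgs, pats, "train")
  expect_s3_class(ds, "slice_dataset")
  expect_length(ds$images, 10)
  # a patient in two splits is rejected
  expect_error(
    assemble_dataset(imgs, pats, c(rep("train", 4), "test", rep("train", 5))),
    "more than one split")
  # masks must match image shapes
  masks <- replicate(10, matrix(FALSE, 3, 3), simplify = FALSE)
  expect_error(slice_dataset(imgs, pats, "test", masks), "dimensions")
  # the training split is normal-only
  good_masks <- replicate(10, matrix(FALSE, 4, 4), simplify = FALSE)
  expect_error(slice_dataset(imgs, pats, "train", good_masks), "normal-only")
})

test_that("manifest round-trips and loads grouped datasets", {
  dir <- tempfile("manif"); dir.create(dir)
  set.seed(4)
  paths <- character(4)
  for (i in 1:4) {
    paths[i] <- file.path(dir, sprintf("im%d.png", i))
    save_slice(matrix(round(runif(16) * 255) / 255, 4, 4), paths[i])
  }
  man <- data.frame(path = basename(paths),
                    patient_id = c("p1", "p1", "p2", "p3"),
                    split = c("train", "train", "test", "test"))
  mf <- file.path(dir, "manifest.tsv")
  write_manifest(man, mf)
  expect_equal(read_manifest(mf), man)
  sets <- load_datasets(mf)
  expect_named(sets, c("train", "test"))
  expect_length(sets$train$images, 2)
  expect_length(sets$test$images, 2)
})
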