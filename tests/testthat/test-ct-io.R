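test_that("NIfTI round-trip preserves voxels, geometry and phase", {
  st <- generate_phantom_pair(tiny_spec(seed = 5))
  path <- file.path(withr::local_tempdir(), "native.nii.gz")
  write_ct(st$native, path)
  back <- read_ct(path)
  expect_equal(back$voxels, st$native$voxels, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$spacing_xy, st$native$spacing_xy, tolerance = 1e-6)
  expect_equal(back$slice_increment, st$native$slice_increment, tolerance = 1e-6)
  expect_equal(back$slice_thickness, st$native$slice_thickness)
  expect_identical(back$phase, "native")
})

test_that("HU rescale is affine and refuses a second application", {
  expect_equal(apply_hu_rescale(1024, slope = 1, intercept = -1024)[1], 0)
  x <- apply_hu_rescale(c(0, 100, 2048), 2, -1024)
  expect_equal(as.numeric(x), c(-1024, -824, 3072))
  expect_error(apply_hu_rescale(x, 2, -1024), "already been rescaled")
})

test_that("a DICOM series written by an independent tool reads back with correct HU and geometry", {
  dir <- withr::local_tempdir()
  script <- sprintf('
import numpy as np, pydicom, os
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
rng = np.random.default_rng(7)
os.makedirs(%s, exist_ok=True)
for i in range(10):
    fm = FileMetaDataset()
    fm.TransferSyntaxUID = ExplicitVRLittleEndian
    fm.MediaStorageSOPClassUID = generate_uid(); fm.MediaStorageSOPInstanceUID = generate_uid()
    ds = Dataset(); ds.file_meta = fm
    ds.Rows = 16; ds.Columns = 16
    ds.PixelSpacing = [0.7, 0.7]; ds.SliceThickness = 3.0
    ds.ImagePositionPatient = [0.0, 0.0, float(2*i)]
    ds.InstanceNumber = i + 1
    ds.RescaleSlope = 1.0; ds.RescaleIntercept = -1024.0
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 0; ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    arr = rng.integers(900, 1200, size=(16,16), dtype=np.uint16)
    if i == 0:
        arr[0,0] = 1024       # stored 1024 -> HU 0
    ds.PixelData = arr.tobytes()
    ds.save_as(os.path.join(%s, f"slice{i:03d}.dcm"), enforce_file_format=True)
', deparse(dir), deparse(dir))
  res <- system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_true(length(list.files(dir)) == 10,
              info = paste(res, collapse = "\n"))
  vol <- read_ct(dir)
  expect_equal(dim(vol$voxels), c(16L, 16L, 10L))
  expect_equal(vol$voxels[1, 1, 1], 0)               # 1024 * 1 - 1024
  expect_equal(vol$spacing_xy, c(0.7, 0.7))
  expect_equal(vol$slice_increment, 2)
  expect_equal(vol$slice_thickness, 3)
  expect_true(all(vol$voxels >= -1024 & vol$voxels <= 4000))
})

test_that("mixed slice spacing within a DICOM series is a hard error", {
  dir <- withr::local_tempdir()
  script <- sprintf('
import numpy as np, os
from pydicom.dataset import Dataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian, generate_uid
os.makedirs(%s, exist_ok=True)
for i, z in enumerate([0.0, 2.0, 5.5]):
    fm = FileMetaDataset(); fm.TransferSyntaxUID = ExplicitVRLittleEndian
    fm.MediaStorageSOPClassUID = generate_uid(); fm.MediaStorageSOPInstanceUID = generate_uid()
    ds = Dataset(); ds.file_meta = fm
    ds.Rows = 4; ds.Columns = 4
    ds.PixelSpacing = [1.0, 1.0]; ds.SliceThickness = 3.0
    ds.ImagePositionPatient = [0.0, 0.0, z]; ds.InstanceNumber = i + 1
    ds.RescaleSlope = 1.0; ds.RescaleIntercept = 0.0
    ds.BitsAllocated = 16; ds.BitsStored = 16; ds.HighBit = 15
    ds.PixelRepresentation = 0; ds.SamplesPerPixel = 1
    ds.PhotometricInterpretation = "MONOCHROME2"
    ds.PixelData = np.full((4,4), 100, dtype=np.uint16).tobytes()
    ds.save_as(os.path.join(%s, f"s{i}.dcm"), enforce_file_format=True)
', deparse(dir), deparse(dir))
  system2("python", "-", input = script, stdout = TRUE, stderr = TRUE)
  expect_error(read_ct(dir), "mixed slice spacing")
})

test_that("phase pairing enforces identical geometry and slice counts", {
  st <- generate_phantom_pair(tiny_spec(seed = 2))
  expect_s3_class(pair_phases(st$native, st$arterial), "ct_study_pair")

  thick <- st$arterial
  thick$slice_thickness <- 5
  expect_error(pair_phases(st$native, thick), "identical pixel spacing")

  short <- st$arterial
  short$voxels <- short$voxels[, , -1, drop = FALSE]
  expect_error(pair_phases(st$native, short), "slice mismatch")

  expect_error(pair_phases(st$arterial, st$native), "native and an arterial")
})

test_that("volumes with implausible HU are rejected at construction", {
  expect_error(flat_volume(hu = -2000), "plausible CT range")
  expect_error(flat_volume(hu = 5000), "plausible CT range")
  expect_silent(flat_volume(hu = -1024))
})
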