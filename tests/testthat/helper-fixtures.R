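# Shared fixture builders.  Everything is generated in code under fixed
# seeds; nothing is read from disk.

# A small preprocessed, image-separable 9-class dataset for training tests.
make_training_dataset <- function(n_lesions = 60, seed = 42,
                                  images_per_lesion = 1,
                                  image_class_signal = TRUE,
                                  metadata_class_signal = FALSE) {
  spec <- synthetic_dataset_spec(
    n_lesions = n_lesions, images_per_lesion = images_per_lesion,
    image_size = c(96L, 96L), seed = seed,
    image_class_signal = image_class_signal,
    metadata_class_signal = metadata_class_signal)
  ds <- gen_lesion_dataset(spec)
  for (i in seq_along(ds$records))
    ds$records[[i]] <- preprocess(ds$records[[i]], target = 64L)$image
  ds
}

# A flat test image with a distinctive gradient (asymmetric, for flip and
# crop identity checks).
gradient_image <- function(h = 32, w = 32) {
  g <- outer(seq(0, 1, length.out = h), seq(0, 1, length.out = w),
             function(a, b) (a + b) / 2)
  array(c(g, g * 0.5, g * 0.25), c(h, w, 3))
}
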