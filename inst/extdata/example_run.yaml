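# Example saclass run configuration: small Siemens-star simulation with
# radially aberrated NA-1.0 pupils and full-strength uniform phase drift.
grid:
  fov: 4.0          # field of view, um
  n: 32             # pixels per side (even)
  wavelength: 0.785 # vacuum wavelength, um
object:
  type: star        # star | blobs | point
  n_spokes: 8
  r_outer: 1.6      # um
  n_blobs: 12       # used by type: blobs
  max_phase: 1.5    # rad, used by type: blobs
  seed: 11
aberration:
  input:
    na: 1.0
    radial_coeffs: [1.0, 1.0, 2.0]   # rho^2, rho^4, rho^6 (rad at pupil edge)
  output:
    na: 1.0
    radial_coeffs: [0.5, 1.5, 2.0]
drift:
  magnitude: 3.141592653589793       # uniform in +-pi
  seed: 7
configuration: sample_plane          # sample_plane | conjugate_plane
solver:
  max_iter: 15
  rel_tol: 1.0e-6
  order: input
  leave_one_out: false
holograms:
  enabled: false
  carrier: null                      # lattice vector [p, q]; null = auto
  ref_amplitude: 1.0
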