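# Reference second-order coefficient sets transcribed from the published
# in-vitro breast-tissue PFG-NMR study that this package reimplements.
# Morphology predictors are raw percentages (p = parenchyma, st = stroma,
# at = adipose tissue, pce = pericellular edema, v = vessels; perivascular
# edema is excluded because it is determined by the other constituents).
# Diffusion predictors are on the regression scale: d_fast in 1e-9 m^2/s,
# d_slow in 1e-11 m^2/s, p1 dimensionless.
# Responses: d_fast in 1e-9 m^2/s, d_slow in 1e-11 m^2/s, p1 dimensionless,
# canp_* are cancer-probability scores on a 0-to-1 scale before clamping.
# Transcription notes:
# - The published fast-phase equation prints an ambiguous exponent on its
#   first quadratic term ("+ 0,001 * P^*"); it is encoded here as the
#   expected squared term p^2. This is an assumption, not a printed fact.
# - The published morphology score mixes decimal separators; all values are
#   encoded as plain period decimals.
model	term	value	reported_r_squared
d_fast	(Intercept)	4.07	0.92
d_fast	p	-0.06	0.92
d_fast	st	-0.09	0.92
d_fast	at	0.03	0.92
d_fast	pce	0.08	0.92
d_fast	v	-0.09	0.92
d_fast	p^2	0.001	0.92
d_fast	st^2	0.001	0.92
d_fast	at^2	-0.001	0.92
d_fast	pce^2	-0.003	0.92
d_fast	v^2	0.005	0.92
d_slow	(Intercept)	2.42	0.81
d_slow	p	0.03	0.81
d_slow	st	-0.07	0.81
d_slow	at	-0.01	0.81
d_slow	pce	-0.13	0.81
d_slow	v	0.08	0.81
d_slow	p^2	-0.001	0.81
d_slow	st^2	0.001	0.81
d_slow	at^2	0.0002	0.81
d_slow	pce^2	0.01	0.81
d_slow	v^2	-0.005	0.81
p1	(Intercept)	1.05	0.93
p1	p	0.02	0.93
p1	st	-0.013	0.93
p1	at	-0.02	0.93
p1	pce	0.07	0.93
p1	v	-0.02	0.93
p1	p^2	-0.0004	0.93
p1	st^2	0.00002	0.93
p1	at^2	0.0002	0.93
p1	pce^2	-0.003	0.93
p1	v^2	0.004	0.93
canp_morphology	(Intercept)	-2.18	0.66
canp_morphology	p	0.099	0.66
canp_morphology	st	0.031	0.66
canp_morphology	at	-0.004	0.66
canp_morphology	pce	-0.02	0.66
canp_morphology	v	0.04	0.66
canp_morphology	p^2	-0.001	0.66
canp_morphology	st^2	-0.0001	0.66
canp_morphology	at^2	0.0004	0.66
canp_morphology	pce^2	0.001	0.66
canp_morphology	v^2	0.0001	0.66
canp_diffusion2	(Intercept)	-3.01	0.69
canp_diffusion2	d_fast	8.02	0.69
canp_diffusion2	d_slow	0.84	0.69
canp_diffusion2	d_fast^2	-2.36	0.69
canp_diffusion2	d_slow^2	0.50	0.69
canp_diffusion2	d_fast:d_slow	-2.78	0.69
canp_diffusion3	(Intercept)	2.71	0.85
canp_diffusion3	d_fast	5.69	0.85
canp_diffusion3	d_slow	-0.59	0.85
canp_diffusion3	p1	-10.21	0.85
canp_diffusion3	d_fast^2	-1.41	0.85
canp_diffusion3	d_slow^2	0.70	0.85
canp_diffusion3	p1^2	1.46	0.85
canp_diffusion3	d_fast:d_slow	-4.19	0.85
canp_diffusion3	d_fast:p1	4.29	0.85
canp_diffusion3	d_slow:p1	2.75	0.85
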