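description: Optimized design vector for level, unloaded walking at the nominal target
  speed (CMA-ES, staged warm-start search; normalized coordinates on the default wiring
  bounds).
target_speed: 1.5
scenario: level, unloaded
design:
- 0.433997857826
- 0.165390674172
- 0.468387771647
- 0.339610376432
- 0.298643238947
- 0.348356284648
- 0.228450909695
- 0.628038732243
- 0.418711026039
- 0.066376237534
- 0.279467326611
- 0.595584825395
- 0.162469411233
- 0.869097779425
- 0.276985482155
- 0.267413578211
- 0.003170103047
- 0.493016996306
- 0.105237543577
- 0.0
- 0.277854588521
- 0.172274384143
- 0.076526648936
- 0.064314742967
- 0.919010837852
- 0.3772455603
- 0.302140204422
- 0.599583909782
- 0.044788404573
- 0.003410028055
- 0.370050538041
- 0.23287400289
- 0.548115430913
- 0.124689962407
- 0.449588302285
- 0.291694505593
- 0.0
- 0.773790169207
- 0.315321511001
- 0.056937657558
- 0.114469000013
- 0.522510925916
- 0.91308557663
- 0.36721933714
- 0.049386801159
- 0.346444686563
- 0.098885738682
- 0.229613774171
- 0.110629352779
- 0.664163815678
- 0.353908248527
- 0.247542213835
- 0.662258477482
- 0.431176258563
- 0.649299556635
- 0.029544766434
- 0.749063951097
- 0.58124960439
- 0.047820556256
- 0.735972392819
- 0.172148301898
- 0.667140197378
- 0.408661783993
- 0.580065298786
- 0.334522834092
- 0.412144394385
- 0.481499059593
- 0.303324128265
- 0.500251966026
- 0.684405814274
- 0.304970633198
- 0.818558467041
- 0.220926909522
- 0.935916141961

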