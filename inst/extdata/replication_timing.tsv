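satellite	timing_class
VfSat1	late
FokI	latest
VfSat2	mid
VfSat3	late
TIII15	late
VfSat4	late
VfSat5	late
pVf7	late
VfSat6	mid
VfSat7	mid
VfSat8	mid
VfSat9	late
VfSat10	mid
VfSat11	late
VfSat12	late
VfSat13	mid
VfSat14	late
VfSat15	late
VfSat16	mid
VfSat17	late
VfSat18	late
VfSat19	late
VfSat20	late
VfSat21	late
VfSat22	late
VfSat23	mid
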