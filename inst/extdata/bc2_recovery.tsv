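plant	family	recovery
BC2-1-1	1	92.53
BC2-1-2	1	91.95
BC2-1-3	1	93.10
BC2-1-4	1	90.80
BC2-1-5	1	93.60
BC2-1-6	1	91.95
BC2-1-7	1	93.68
BC2-1-8	1	92.44
BC2-5-1	5	90.70
BC2-5-2	5	93.10
BC2-5-3	5	93.60
BC2-5-4	5	90.80
BC2-5-5	5	94.25
BC2-5-6	5	91.38
BC2-5-7	5	91.95
BC2-5-8	5	87.93
BC2-5-9	5	93.68
BC2-5-10	5	91.86
BC2-5-12	5	89.08
BC2-5-15	5	94.77
BC2-8-1	8	90.80
BC2-8-2	8	92.53
BC2-8-3	8	93.68
BC2-8-4	8	93.10
BC2-8-6	8	94.25
BC2-8-8	8	92.53
BC2-8-9	8	94.25
BC2-8-10	8	93.10
BC2-8-11	8	91.95
BC2-8-12	8	89.53
BC2-8-13	8	93.68
BC2-35-1	35	90.23
BC2-35-2	35	89.53
BC2-35-3	35	88.51
BC2-35-4	35	91.38
BC2-35-5	35	90.80
BC2-35-6	35	90.23
BC2-35-7	35	89.08
BC2-35-8	35	90.23
BC2-35-9	35	91.95
BC2-36-1	36	93.10
BC2-36-2	36	90.80
BC2-36-3	36	94.25
BC2-36-4	36	90.23
BC2-36-5	36	91.95
BC2-36-7	36	92.44
BC2-36-8	36	90.36
BC2-36-9	36	88.37
BC2-36-10	36	92.44
BC2-36-11	36	92.35
BC2-36-12	36	95.40
BC2-47-1	47	92.44
BC2-47-2	47	93.53
BC2-47-3	47	90.80
BC2-47-4	47	94.25
BC2-47-5	47	90.23
BC2-47-6	47	89.66
BC2-47-7	47	94.25
BC2-47-8	47	93.10
BC2-83-1	83	94.19
BC2-83-2	83	89.08
BC2-83-4	83	91.38
BC2-83-5	83	93.10
BC2-83-6	83	93.10
BC2-83-7	83	92.77
BC2-83-8	83	90.23
BC2-83-9	83	90.80
BC2-83-10	83	89.66
BC2-83-11	83	93.02
BC2-83-12	83	92.94
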