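S01_read0001	strain_01
S01_read0002	strain_01
S01_read0003	strain_01
S01_read0004	strain_01
S01_read0005	strain_01
S01_read0006	strain_01
S01_read0007	strain_01
S01_read0008	strain_01
S01_read0009	strain_01
S01_read0010	strain_01
S01_read0011	strain_01
S01_read0012	strain_01
S01_read0013	strain_01
S01_read0014	strain_01
S01_read0015	strain_01
S02_read0001	strain_02
S02_read0002	strain_02
S02_read0003	strain_02
S02_read0004	strain_02
S02_read0005	strain_02
S02_read0006	strain_02
S02_read0007	strain_02
S02_read0008	strain_02
S02_read0009	strain_02
S02_read0010	strain_02
S02_read0011	strain_02
S02_read0012	strain_02
S02_read0013	strain_02
S02_read0014	strain_02
S02_read0015	strain_02
S03_read0001	strain_03
S03_read0002	strain_03
S03_read0003	strain_03
S03_read0004	strain_03
S03_read0005	strain_03
S03_read0006	strain_03
S03_read0007	strain_03
S03_read0008	strain_03
S03_read0009	strain_03
S03_read0010	strain_03
S03_read0011	strain_03
S03_read0012	strain_03
S03_read0013	strain_03
S03_read0014	strain_03
S03_read0015	strain_03
S04_read0001	strain_04
S04_read0002	strain_04
S04_read0003	strain_04
S04_read0004	strain_04
S04_read0005	strain_04
S04_read0006	strain_04
S04_read0007	strain_04
S04_read0008	strain_04
S04_read0009	strain_04
S04_read0010	strain_04
S04_read0011	strain_04
S04_read0012	strain_04
S04_read0013	strain_04
S04_read0014	strain_04
S04_read0015	strain_04
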