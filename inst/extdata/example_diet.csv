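lake_id,fish_id,prey_order,life_stage,habitat,length_mm
L01,L01_f01,Coleoptera,adult,aquatic,
L01,L01_f01,Hymenoptera,adult,terrestrial,71.9
L01,L01_f01,Hymenoptera,adult,terrestrial,4.5
L01,L01_f01,Diptera,juvenile,aquatic,6.6
L01,L01_f01,Diptera,juvenile,aquatic,11
L01,L01_f01,Diptera,juvenile,aquatic,8.6
L01,L01_f01,Coleoptera,adult,aquatic,5.1
L01,L01_f01,Diptera,juvenile,aquatic,6.7
L01,L01_f02,Diptera,juvenile,aquatic,3.7
L01,L01_f02,Diptera,juvenile,aquatic,23
L01,L01_f02,Coleoptera,adult,aquatic,4.2
L01,L01_f02,Diptera,juvenile,aquatic,5.1
L01,L01_f02,Diptera,juvenile,aquatic,3.3
L01,L01_f02,Hymenoptera,adult,terrestrial,6
L01,L01_f03,Trichoptera,juvenile,aquatic,9.2
L01,L01_f03,Trichoptera,juvenile,aquatic,5.6
L01,L01_f03,Trichoptera,juvenile,aquatic,3.2
L01,L01_f03,Diptera,juvenile,aquatic,3.4
L01,L01_f04,Diptera,juvenile,aquatic,8.4
L01,L01_f04,Diptera,juvenile,aquatic,2.3
L01,L01_f04,Ephemeroptera,juvenile,aquatic,16.8
L01,L01_f04,Ephemeroptera,juvenile,aquatic,16
L01,L01_f04,Diptera,juvenile,aquatic,3.3
L01,L01_f04,Diptera,juvenile,aquatic,2.4
L01,L01_f04,Diptera,juvenile,aquatic,10.1
L01,L01_f04,Ephemeroptera,juvenile,aquatic,7.2
L01,L01_f05,Diptera,juvenile,aquatic,13.5
L01,L01_f05,Coleoptera,adult,aquatic,29.3
L01,L01_f05,Diptera,juvenile,aquatic,10.9
L01,L01_f06,Ephemeroptera,juvenile,aquatic,7.4
L01,L01_f06,Trichoptera,juvenile,aquatic,18
L01,L01_f06,Coleoptera,adult,aquatic,3.5
L01,L01_f06,Coleoptera,adult,aquatic,14.1
L01,L01_f06,Ephemeroptera,juvenile,aquatic,
L01,L01_f06,Ephemeroptera,juvenile,aquatic,7.3
L01,L01_f06,Diptera,juvenile,aquatic,9.8
L02,L02_f01,Diptera,juvenile,aquatic,1.7
L02,L02_f01,Hymenoptera,adult,terrestrial,5.2
L02,L02_f01,Hymenoptera,adult,terrestrial,
L02,L02_f01,Diptera,juvenile,aquatic,4.1
L02,L02_f01,Hymenoptera,adult,terrestrial,7.6
L02,L02_f01,Diptera,juvenile,aquatic,2.9
L02,L02_f02,Ephemeroptera,juvenile,aquatic,
L02,L02_f02,Ephemeroptera,juvenile,aquatic,8.7
L02,L02_f02,Diptera,juvenile,aquatic,7.3
L02,L02_f02,Ephemeroptera,juvenile,aquatic,6.6
L02,L02_f02,Ephemeroptera,juvenile,aquatic,7.2
L02,L02_f02,Ephemeroptera,juvenile,aquatic,7
L02,L02_f03,Diptera,juvenile,aquatic,10.3
L02,L02_f03,Diptera,juvenile,aquatic,12
L02,L02_f03,Diptera,juvenile,aquatic,11.2
L02,L02_f03,Diptera,juvenile,aquatic,8.8
L02,L02_f03,Diptera,juvenile,aquatic,14.6
L02,L02_f03,Diptera,juvenile,aquatic,11.6
L02,L02_f03,Diptera,juvenile,aquatic,14.3
L02,L02_f03,Diptera,juvenile,aquatic,11.4
L02,L02_f03,Diptera,juvenile,aquatic,10.8
L02,L02_f04,Ephemeroptera,juvenile,aquatic,9.3
L02,L02_f04,Ephemeroptera,juvenile,aquatic,3.8
L02,L02_f04,Ephemeroptera,juvenile,aquatic,3.4
L02,L02_f04,Ephemeroptera,juvenile,aquatic,4
L02,L02_f04,Coleoptera,adult,aquatic,9.4
L02,L02_f04,Ephemeroptera,juvenile,aquatic,6.5
L02,L02_f04,Coleoptera,adult,aquatic,9.1
L02,L02_f04,Ephemeroptera,juvenile,aquatic,4.5
L02,L02_f05,Hymenoptera,adult,terrestrial,9.1
L02,L02_f05,Ephemeroptera,juvenile,aquatic,4.3
L02,L02_f05,Odonata,juvenile,aquatic,
L02,L02_f05,Hymenoptera,adult,terrestrial,3.6
L02,L02_f05,Hymenoptera,adult,terrestrial,3.7
L02,L02_f05,Hymenoptera,adult,terrestrial,4.1
L02,L02_f05,Hymenoptera,adult,terrestrial,6.7
L02,L02_f05,Diptera,juvenile,aquatic,4.7
L02,L02_f05,Hymenoptera,adult,terrestrial,3.2
L02,L02_f05,Diptera,juvenile,aquatic,6.4
L02,L02_f06,Diptera,juvenile,aquatic,2.2
L02,L02_f06,Diptera,juvenile,aquatic,2.2
L02,L02_f06,Diptera,juvenile,aquatic,3.3
L02,L02_f06,Ephemeroptera,juvenile,aquatic,6.3
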