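# Synthetic four-motif CD reference basis, version 1.1
# Gaussian-sum approximations of classic poly-peptide motif band shapes
# (alpha-helix 208/222 nm minima, beta-sheet 216 nm minimum, class-B
# beta-turn couplet, random coil ~197 nm minimum), mean residue
# ellipticity in deg cm2/dmol on a 200-240 nm grid at 0.5 nm pitch.
# Synthetic construction; not a measured dataset.
"wavelength_nm","helix","sheet","turn","coil"
200,14915.8,24456.6,6291.7,-36965
200.5,10928.4,22635.2,6710.8,-35467
201,6949.4,20767.7,7106.7,-33811.9
201.5,3006.6,18875.4,7471.6,-32024.7
202,-871.9,16977.4,7798.1,-30131.4
202.5,-4657,15089.9,8079.3,-28158.1
203,-8320.2,13225.9,8308.5,-26131.3
203.5,-11833.2,11395.2,8480,-24076.3
204,-15169.2,9604.7,8588.8,-22017.3
204.5,-18303.2,7857.9,8631.2,-19976.7
205,-21212.8,6156,8604.6,-17975
205.5,-23878.8,4497.9,8507.4,-16030
206,-26286.1,2881.1,8339.6,-14157.3
206.5,-28424.2,1301.7,8102.2,-12369.7
207,-30287.6,-244.1,7797.6,-10677.2
207.5,-31876,-1760.2,7429.2,-9087.4
208,-33194.9,-3249.6,7001.3,-7605.2
208.5,-34255.2,-4713.8,6519.1,-6233.6
209,-35073.1,-6152.5,5988.6,-4973.1
209.5,-35669.8,-7563.3,5416.1,-3822.6
210,-36070.7,-8941.5,4808,-2779.5
210.5,-36304.5,-10279.8,4171.3,-1839.8
211,-36402.5,-11569,3512.4,-998.6
211.5,-36397.2,-12797.6,2837.8,-250.3
212,-36321.6,-13952.5,2153.6,411.2
212.5,-36207.4,-15019.8,1465.3,992.5
213,-36084.4,-15984.9,778.1,1499.9
213.5,-35978.9,-16833.4,96.7,1939.9
214,-35913.1,-17551.9,-575.2,2318.7
214.5,-35904.2,-18128.4,-1233.8,2642.3
215,-35963.7,-18553.2,-1876.3,2916.1
215.5,-36097.4,-18819.5,-2500.2,3145.4
216,-36304.6,-18923.4,-3103.4,3334.8
216.5,-36578.9,-18864.7,-3684.1,3488.7
217,-36908.3,-18646.4,-4240.8,3610.7
217.5,-37276,-18275.4,-4772,3704.4
218,-37661,-17761.9,-5276.8,3772.7
218.5,-38039.2,-17118.8,-5753.8,3818.2
219,-38384.5,-16362,-6202,3843.4
219.5,-38670,-15509,-6620.4,3850.2
220,-38869.2,-14578.8,-7007.8,3840.6
220.5,-38956.9,-13591.2,-7363.1,3816
221,-38910.6,-12565.9,-7685.4,3778
221.5,-38711.4,-11522,-7973.5,3727.8
222,-38344.4,-10477.9,-8226.4,3666.7
222.5,-37799.6,-9449.8,-8443.2,3595.7
223,-37072.1,-8452.3,-8623.1,3515.9
223.5,-36162.1,-7497.9,-8765.6,3428.2
224,-35075.1,-6596.5,-8870.2,3333.6
224.5,-33821.4,-5755.7,-8936.7,3232.8
225,-32415.6,-4980.7,-8965.2,3126.9
225.5,-30876,-4274.6,-8956.2,3016.5
226,-29223.9,-3638.4,-8910.3,2902.6
226.5,-27482.6,-3071.3,-8828.5,2785.8
227,-25677.1,-2571.3,-8712.3,2666.9
227.5,-23832.4,-2135,-8563.1,2546.6
228,-21973.5,-1758.2,-8383.1,2425.6
228.5,-20124.1,-1435.9,-8174.4,2304.6
229,-18306.4,-1163.1,-7939.5,2184.1
229.5,-16540.3,-934.3,-7680.9,2064.7
230,-14843.1,-744.4,-7401.7,1946.9
230.5,-13229.4,-588.2,-7104.6,1831.3
231,-11710.6,-460.9,-6792.8,1718.2
231.5,-10295.1,-358.2,-6469.3,1608.1
232,-8988.7,-276.1,-6137.1,1501.2
232.5,-7794.1,-211.1,-5799.3,1398
233,-6711.8,-160,-5458.6,1298.6
233.5,-5740,-120.3,-5117.9,1203.3
234,-4875.1,-89.7,-4779.8,1112.1
234.5,-4111.9,-66.4,-4446.6,1025.4
235,-3444.3,-48.7,-4120.5,943
235.5,-2865.1,-35.4,-3803.4,865.1
236,-2366.9,-25.5,-3497,791.6
236.5,-1941.8,-18.3,-3202.8,722.6
237,-1582,-13,-2921.9,657.9
237.5,-1280,-9.1,-2655.2,597.5
238,-1028.5,-6.4,-2403.5,541.3
238.5,-820.7,-4.4,-2167.1,489.2
239,-650.3,-3,-1946.4,441
239.5,-511.8,-2.1,-1741.3,396.5
240,-399.9,-1.4,-1551.8,355.7
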